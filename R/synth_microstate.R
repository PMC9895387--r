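## Synthetic resting-EEG generator with known microstate dynamics: piecewise
## stable dipolar topographies with semi-Markov dwell structure riding an
## in-band oscillatory carrier that vanishes at dwell boundaries (so global
## field power has realistic local peaks and troughs at transitions),
## random polarity flips per dwell, and white sensor noise.

#' Specification of a synthetic microstate EEG generator
#'
#' Collects the ground-truth parameters of the semi-Markov topography
#' generator. Defaults give a 4-state, 120-ms mean-dwell process at 250 Hz
#' riding an alpha-band carrier, with a signal-to-noise ratio
#' (`gfp_scale / noise_sd`) of 5.
#'
#' @param n_states Number of microstate classes K.
#' @param templates Optional K x channels matrix of zero-mean unit-norm
#'   template maps; generated by [make_template_maps()] when `NULL`.
#' @param mean_duration_ms Mean dwell per state, ms (scalar or length K).
#' @param transition_bias K x K stochastic matrix with zero diagonal driving
#'   the embedded state chain; default uniform over the other states.
#' @param gfp_scale Mean global field power of the signal at unit envelope,
#'   microvolts.
#' @param noise_sd Sensor noise standard deviation, microvolts.
#' @param fs_hz Sampling rate, Hz.
#' @param length_s Recording length, seconds.
#' @param dwell Dwell-time law: `"gamma"` (default, shape `dwell_shape`;
#'   matches the peaked, non-memoryless dwell histograms of resting EEG) or
#'   `"geometric"` (memoryless).
#' @param dwell_shape Gamma shape when `dwell = "gamma"`.
#' @param carrier_band Frequency band (Hz) of the oscillatory amplitude
#'   carrier the topographies ride on; its rectified value is the
#'   noise-free GFP, so the carrier controls the spacing of GFP peaks
#'   (default 9-13 Hz: the alpha rhythm that dominates resting GFP).
#' @param flip_prob Probability of a polarity flip at each dwell onset (the
#'   signed carrier already alternates polarity within dwells; both are
#'   ignored by the polarity-invariant analyses).
#' @param render_band Band (Hz) to which each state's gated signal is
#'   limited when rendering (default 2-20): microstate structure in resting
#'   EEG is a band-limited phenomenon, so state transitions are smooth in
#'   the data itself rather than instantaneous. `NULL` disables.
#' @param seed Integer seed for all randomness of this generator.
#' @return An object of class `msgen_spec`.
#' @export
msgen_spec <- function(n_states = 4, templates = NULL,
                       mean_duration_ms = 120, transition_bias = NULL,
                       gfp_scale = 10, noise_sd = 2,
                       fs_hz = 250, length_s = 180,
                       dwell = c("gamma", "geometric"), dwell_shape = 4,
                       carrier_band = c(9, 13), flip_prob = 0.5,
                       render_band = c(2, 20), seed = 1L) {
  dwell <- match.arg(dwell)
  stop_if(n_states < 1, "n_states must be >= 1")
  mean_duration_ms <- rep_len(mean_duration_ms, n_states)
  stop_if(any(mean_duration_ms <= 0), "mean durations must be positive")
  if (is.null(transition_bias)) {
    transition_bias <- matrix(1 / max(n_states - 1, 1), n_states, n_states)
    diag(transition_bias) <- 0
  }
  check_stochastic_zero_diag(transition_bias, n_states)
  stop_if(fs_hz <= 0 || length_s <= 0 || fs_hz * length_s < 1,
          "fs_hz * length_s must be at least one sample")
  stop_if(gfp_scale <= 0 || noise_sd < 0, "invalid amplitude parameters")
  structure(list(n_states = n_states, templates = templates,
                 mean_duration_ms = mean_duration_ms,
                 transition_bias = transition_bias, gfp_scale = gfp_scale,
                 noise_sd = noise_sd, fs_hz = fs_hz, length_s = length_s,
                 dwell = dwell, dwell_shape = dwell_shape,
                 carrier_band = carrier_band, flip_prob = flip_prob,
                 render_band = render_band, seed = as.integer(seed)),
            class = "msgen_spec")
}

check_stochastic_zero_diag <- function(P, k) {
  stop_if(!is.matrix(P) || nrow(P) != k || ncol(P) != k,
          "transition matrix must be %d x %d", k, k)
  stop_if(any(diag(P) != 0), "transition matrix must have a zero diagonal")
  stop_if(any(P < 0), "transition probabilities must be non-negative")
  if (k > 1)
    stop_if(any(abs(rowSums(P) - 1) > 1e-8),
            "transition matrix rows must sum to 1")
  invisible(TRUE)
}

#' Generate random microstate template topographies
#'
#' Each template is the scalp potential of a random current dipole inside a
#' unit sphere (single-sphere closed form), mean-removed and normalized to
#' unit Euclidean norm, giving physiologically plausible smooth dipolar maps.
#' Candidates are redrawn until all pairwise absolute spatial correlations
#' are below `max_abs_corr`.
#'
#' @param n_states Number of maps.
#' @param montage Electrode montage data frame (see [montage_1010()]).
#' @param seed Integer seed.
#' @param max_abs_corr Pairwise absolute-correlation ceiling (default 0.9).
#' @param max_tries Resampling budget per map before giving up.
#' @return `n_states` x channels matrix of zero-mean unit-norm rows.
#' @export
make_template_maps <- function(n_states, montage, seed = 1L,
                               max_abs_corr = 0.9, max_tries = 200) {
  stop_if(n_states < 1, "n_states must be >= 1")
  stop_if(nrow(montage) < 2, "montage needs at least 2 electrodes")
  el <- as.matrix(montage[, c("x", "y", "z")])
  with_seed(seed, {
    maps <- matrix(0, n_states, nrow(el))
    for (i in seq_len(n_states)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        pos <- stats::runif(3, -1, 1)
        pos <- pos / max(sqrt(sum(pos^2)), 1e-9) * stats::runif(1, 0.2, 0.6)
        mom <- stats::rnorm(3)
        v <- dipole_map_homogeneous(pos, mom, el)
        v <- v - mean(v)
        nv <- sqrt(sum(v^2))
        if (nv < 1e-9) next
        v <- v / nv
        if (i == 1 || max(map_corr_matrix(maps[seq_len(i - 1), , drop = FALSE],
                                          matrix(v, 1))) < max_abs_corr) {
          maps[i, ] <- v
          ok <- TRUE
          break
        }
      }
      stop_if(!ok, paste0("could not draw %d templates with pairwise |corr| < ",
                          "%g in %d tries"), n_states, max_abs_corr, max_tries)
    }
    maps
  })
}

## scalp potential of a dipole in a homogeneous unit sphere (closed form),
## used only as a realistic map generator here; see leadfield_homogeneous()
dipole_map_homogeneous <- function(pos, mom, electrodes) {
  leadfield_homogeneous(electrodes, matrix(pos, 1), matrix(mom, 1))[, 1]
}

## |Pearson correlation| between all rows of A and rows of B (maps are
## mean-removed first)
map_corr_matrix <- function(A, B) {
  A <- sweep(A, 1, rowMeans(A))
  B <- sweep(B, 1, rowMeans(B))
  A <- A / sqrt(rowSums(A^2) + 1e-300)
  B <- B / sqrt(rowSums(B^2) + 1e-300)
  abs(A %*% t(B))
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Dwell lengths are drawn per state with the specified mean (geometric by
#' default, optionally gamma); successive states follow the embedded chain
#' `transition_bias`.
#'
#' @param spec An [msgen_spec()].
#' @return Integer vector of per-sample state labels (length `fs * length`),
#'   with the dwell lengths in samples as attribute `"dwells"` and the state
#'   of each dwell as `"dwell_states"`.
#' @export
simulate_state_sequence <- function(spec) {
  k <- spec$n_states
  n <- round(spec$fs_hz * spec$length_s)
  mean_samp <- spec$mean_duration_ms * spec$fs_hz / 1000
  with_seed(spec$seed, {
    states <- integer(0); dwells <- integer(0)
    s <- sample.int(k, 1)
    total <- 0
    while (total < n) {
      d <- draw_dwell(spec, mean_samp[s])
      states <- c(states, s); dwells <- c(dwells, d)
      total <- total + d
      s <- if (k > 1) sample.int(k, 1, prob = spec$transition_bias[s, ]) else 1L
    }
    labels <- rep(states, dwells)[seq_len(n)]
    attr(labels, "dwells") <- dwells
    attr(labels, "dwell_states") <- states
    labels
  })
}

draw_dwell <- function(spec, mean_samp) {
  if (spec$dwell == "geometric") {
    ## support >= 1 with mean `mean_samp`
    p <- 1 / max(mean_samp, 1)
    stats::rgeom(1, p) + 1L
  } else {
    max(1L, as.integer(round(stats::rgamma(1, shape = spec$dwell_shape,
                                           scale = mean_samp / spec$dwell_shape))))
  }
}

#' Render a label sequence into synthetic EEG
#'
#' Sample `t` is `gfp_scale * a(t) * sign(dwell) * template[label(t)]`
#' (scaled so the noise-free global field power equals
#' `gfp_scale * |a(t)|`) plus white Gaussian sensor noise. The carrier
#' `a(t)` is band-limited Gaussian noise normalized to unit root mean
#' square, so topographies wax and wane like in-band oscillations and the
#' GFP series has realistic local peaks; polarity (carrier sign and
#' per-dwell flips) carries no information for the polarity-invariant
#' analyses.
#'
#' @param labels Integer label sequence from [simulate_state_sequence()].
#' @param spec An [msgen_spec()] (must carry `templates`; see
#'   [make_template_maps()]).
#' @param montage Electrode montage matching the templates.
#' @return An [eeg_recording()] with a `ground_truth` attribute recording
#'   the rendered per-sample ground-truth labels (`labels`, the dominant
#'   state of the band-limited rendering), the nominal `planted_labels`,
#'   per-dwell signs and the carrier envelope.
#' @export
render_eeg <- function(labels, spec, montage) {
  tpl <- spec$templates
  stop_if(is.null(tpl), "spec$templates is NULL; run make_template_maps() first")
  n <- round(spec$fs_hz * spec$length_s)
  stop_if(length(labels) != n,
          "labels length (%d) does not match fs * length (%d)", length(labels), n)
  C <- ncol(tpl)
  stop_if(nrow(montage) != C, "montage does not match template channels")
  with_seed(spec$seed + 1L, {
    env <- carrier_series(n, spec$carrier_band, spec$fs_hz)
    runs <- rle(as.integer(labels))
    ## amplitude vanishes at dwell boundaries (microstate transitions occur
    ## at troughs of the global field power), so each dwell carries a smooth
    ## rise-and-fall of its own topography
    taper <- unlist(lapply(runs$lengths, function(d)
      sqrt(sin(pi * (seq_len(d) - 0.5) / d))))
    env <- env * taper
    env <- env / sqrt(mean(env^2))
    ## per-dwell polarity
    signs_run <- ifelse(stats::runif(length(runs$lengths)) < spec$flip_prob, -1, 1)
    signs <- rep(signs_run, runs$lengths)
    ## unit-norm zero-mean template has spatial sd 1/sqrt(C); rescale so the
    ## noise-free GFP equals gfp_scale * env
    amp <- spec$gfp_scale * sqrt(C) * env * signs
    ## per-state gated amplitude series, band-limited so transitions are
    ## smooth within the analysis band (as in real EEG)
    K <- nrow(tpl)
    Gm <- matrix(0, K, n)
    Gm[cbind(labels, seq_len(n))] <- amp
    if (!is.null(spec$render_band)) {
      nt <- fir_ntaps(max(0.25 * spec$render_band[1], 0.5), spec$fs_hz)
      h <- signal::fir1(nt - 1, spec$render_band / (spec$fs_hz / 2),
                        type = "pass")
      Gm <- fir_apply(Gm, h)
    }
    X <- t(tpl) %*% Gm
    ## effective (rendered) truth: band-limiting smooths state transitions,
    ## so the dominant state near a boundary can shift by a few samples --
    ## the state dominating the rendered local signal power is the ground
    ## truth of the data (power smoothed over ~a carrier cycle so carrier
    ## zero crossings do not flicker the labels)
    sm_sd <- 0.02 * spec$fs_hz
    half <- ceiling(3 * sm_sd)
    kern <- stats::dnorm(seq(-half, half), sd = sm_sd)
    kern <- kern / sum(kern)
    Pw <- t(apply(Gm^2, 1, function(g)
      stats::filter(c(rep(0, half), g, rep(0, half)), kern,
                    sides = 2)[(half + 1):(half + n)]))
    eff <- max.col(t(Pw), ties.method = "first")
    if (spec$noise_sd > 0)
      X <- X + matrix(stats::rnorm(C * n, sd = spec$noise_sd), C, n)
    rec <- eeg_recording(X, spec$fs_hz, montage)
    attr(rec, "ground_truth") <- list(labels = as.integer(eff),
                                      planted_labels = as.integer(labels),
                                      signs = signs, envelope = env,
                                      templates = tpl)
    rec
  })
}

## band-limited Gaussian carrier, unit rms
carrier_series <- function(n, band, fs_hz) {
  drop(bandlimited_noise(1, n, band, fs_hz))
}

#' Simulate one synthetic microstate EEG recording
#'
#' Convenience wrapper: draws templates if needed, simulates the label
#' sequence and renders the recording.
#'
#' @param spec An [msgen_spec()].
#' @param montage Electrode montage (default [montage_1010()]).
#' @return An [eeg_recording()] with the `ground_truth` attribute.
#' @export
simulate_microstate_eeg <- function(spec, montage = montage_1010()) {
  if (is.null(spec$templates))
    spec$templates <- make_template_maps(spec$n_states, montage, spec$seed)
  labels <- simulate_state_sequence(spec)
  render_eeg(labels, spec, montage)
}

#' Analytic microstate statistics implied by a generator specification
#'
#' Computes, from the embedded chain and mean dwell times, the stationary
#' expectation of the standard temporal parameters: mean duration (ms),
#' occurrences per second, fraction of time covered, and the matrix of
#' observed switch fractions (stationary probability of an `i -> j` switch
#' among all switches).
#'
#' @param spec An [msgen_spec()].
#' @return List with `duration_ms`, `occurrence_per_s`, `coverage`,
#'   `transition_probs` (K x K, zero diagonal, summing to 1).
#' @export
expected_state_stats <- function(spec) {
  k <- spec$n_states
  mu_s <- spec$mean_duration_ms / 1000
  if (k == 1) {
    return(list(duration_ms = spec$mean_duration_ms, occurrence_per_s = 0,
                coverage = 1,
                transition_probs = matrix(0, 1, 1)))
  }
  nu <- stationary_distribution(spec$transition_bias)
  cycle <- sum(nu * mu_s)               # mean dwell per run, seconds
  coverage <- nu * mu_s / cycle
  occurrence <- nu / cycle
  tp <- spec$transition_bias * nu       # row i scaled by nu_i
  list(duration_ms = spec$mean_duration_ms,
       occurrence_per_s = occurrence,
       coverage = coverage,
       transition_probs = tp / sum(tp))
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}
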