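## Two-condition within-subject cohorts with planted effects: each subject
## contributes a "pre" and a "post" recording pair (microstate EEG and
## network-rhythm EEG); "post" applies named multipliers to the base
## generator parameters, and a ledger records the exact planted values.

#' Specification of a synthetic pre/post cohort
#'
#' The five recognized effects, applied in the "post" condition:
#' \describe{
#'   \item{state_C_duration}{multiplies the mean dwell of state C}
#'   \item{state_D_coverage}{multiplies the stationary time coverage of
#'     state D (achieved by an exact analytic rescaling of state D's mean
#'     dwell)}
#'   \item{AC_transition}{multiplies the A-to-C and C-to-A entries of the
#'     embedded transition chain (rows renormalized)}
#'   \item{BD_transition}{same for B and D}
#'   \item{visual_beta2}{multiplies the visual-network beta2-band source
#'     amplitude}
#' }
#' Multipliers of 1 give a null cohort.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param effects Named list of positive multipliers (see above). Missing
#'   entries default to 1.
#' @param base_ms Base [msgen_spec()] shared by all subjects.
#' @param base_net Base [netgen_spec()]; its `band_hz` selects the planted
#'   band and its `active_network` the planted network for `visual_beta2`.
#' @param background_amp Amplitude of the multi-band background on every
#'   network (see the cohort renderer).
#' @param net_noise_sd Sensor noise of the network-rhythm recordings.
#' @param seed Master seed; per-subject, per-condition seeds derive from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, effects = list(),
                        base_ms = msgen_spec(), base_net = netgen_spec(),
                        background_amp = 1, net_noise_sd = 0.5, seed = 1L) {
  stop_if(n_subjects < 2, "need at least 2 subjects")
  known <- c("state_C_duration", "state_D_coverage", "AC_transition",
             "BD_transition", "visual_beta2")
  stop_if(!all(names(effects) %in% known), "unknown effect(s): %s",
          paste(setdiff(names(effects), known), collapse = ", "))
  eff <- stats::setNames(rep(1, length(known)), known)
  eff[names(effects)] <- unlist(effects)
  stop_if(any(eff <= 0), "multipliers must be positive")
  structure(list(n_subjects = n_subjects, effects = as.list(eff),
                 base_ms = base_ms, base_net = base_net,
                 background_amp = background_amp,
                 net_noise_sd = net_noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

## dwell multiplier for state `s` that sets its stationary coverage to the
## absolute target c*: with nu the stationary chain, T = sum(nu mu) and
## c_s = nu_s mu_s, coverage_s(f mu_s) = c* solves to
## f = c* (T - c_s) / (c_s (1 - c*))
dwell_factor_for_coverage <- function(spec, s, target) {
  nu <- stationary_distribution(spec$transition_bias)
  mu <- spec$mean_duration_ms
  Tm <- sum(nu * mu); cs <- nu[s] * mu[s]
  stop_if(target <= 0 || target >= 1, "target coverage %g infeasible", target)
  target * (Tm - cs) / (cs * (1 - target))
}

## post-condition microstate generator spec implied by the effects; the D
## dwell rescaling is solved on the fully updated chain so the planted
## post/pre coverage ratio is exact
apply_ms_effects <- function(base, effects) {
  post <- base
  post$mean_duration_ms[3] <- post$mean_duration_ms[3] *
    effects$state_C_duration
  P <- post$transition_bias
  P[1, 3] <- P[1, 3] * effects$AC_transition
  P[3, 1] <- P[3, 1] * effects$AC_transition
  P[2, 4] <- P[2, 4] * effects$BD_transition
  P[4, 2] <- P[4, 2] * effects$BD_transition
  post$transition_bias <- P / rowSums(P)
  if (effects$state_D_coverage != 1) {
    target <- effects$state_D_coverage * expected_state_stats(base)$coverage[4]
    post$mean_duration_ms[4] <- post$mean_duration_ms[4] *
      dwell_factor_for_coverage(post, 4, target)
  }
  post
}

#' Simulate a pre/post cohort with planted effects
#'
#' Every subject gets independent pre and post recordings. Microstate EEG
#' uses shared templates across subjects (drawn once from the base seed);
#' network EEG uses a multi-band background on all networks with the
#' planted amplitude multiplier applied in "post". The returned ledger
#' holds, per condition, the analytic expected microstate statistics and
#' the planted amplitude tables.
#'
#' @param spec A [cohort_spec()].
#' @param montage Electrode montage.
#' @param lead Optional `leadfield` (with `priors`' atlas) for the
#'   network-rhythm arm; when `NULL` only microstate recordings are
#'   generated.
#' @param atlas `network_atlas` matching `lead`.
#' @param bands [band_definition()] used for the background.
#' @return Object of class `eeg_cohort`: `subjects` (list with `pre` /
#'   `post`, each holding `ms` and optionally `net` recordings), `ledger`,
#'   and the specs used.
#' @export
simulate_cohort <- function(spec, montage = montage_1010(), lead = NULL,
                            atlas = NULL, bands = band_definition()) {
  base <- spec$base_ms
  if (is.null(base$templates))
    base$templates <- make_template_maps(base$n_states, montage, base$seed)
  post <- apply_ms_effects(base, spec$effects)
  net_on <- !is.null(lead)
  if (net_on) stop_if(is.null(atlas), "atlas required with a lead field")
  amp_pre <- amp_post <- NULL
  if (net_on) {
    nb <- nrow(bands)
    amp_pre <- matrix(spec$background_amp, length(atlas$names), nb,
                      dimnames = list(atlas$names, bands$name))
    amp_post <- amp_pre
    net <- resolve_network(spec$base_net$active_network, atlas)
    b2 <- which(bands$low_hz <= spec$base_net$band_hz[1] &
                  bands$high_hz >= spec$base_net$band_hz[2])[1]
    stop_if(is.na(b2), "planted band does not match any analysis band")
    amp_post[net, b2] <- amp_post[net, b2] * spec$effects$visual_beta2
  }
  seeds <- derive_seeds(spec$seed, spec$n_subjects * 4)
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sd4 <- seeds[(s - 1) * 4 + 1:4]
    mk <- function(gen, seed_i) {
      g <- gen; g$seed <- seed_i
      simulate_microstate_eeg(g, montage)
    }
    subj <- list(pre = list(ms = mk(base, sd4[1])),
                 post = list(ms = mk(post, sd4[2])))
    if (net_on) {
      subj$pre$net <- simulate_multiband_network_eeg(
        amp_pre, bands, lead, atlas, spec$base_net$fs_hz,
        spec$base_net$length_s, spec$net_noise_sd, sd4[3])
      subj$post$net <- simulate_multiband_network_eeg(
        amp_post, bands, lead, atlas, spec$base_net$fs_hz,
        spec$base_net$length_s, spec$net_noise_sd, sd4[4])
    }
    subjects[[s]] <- subj
  }
  ledger <- list(effects = spec$effects,
                 expected_pre = expected_state_stats(base),
                 expected_post = expected_state_stats(post),
                 amp_pre = amp_pre, amp_post = amp_post,
                 templates = base$templates,
                 ms_spec_pre = base, ms_spec_post = post)
  structure(list(subjects = subjects, ledger = ledger, spec = spec,
                 montage = montage, lead = lead, atlas = atlas,
                 bands = bands),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects x 2 conditions (%s network arm)\n",
              length(x$subjects),
              if (is.null(x$lead)) "no" else "with"))
  invisible(x)
}
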