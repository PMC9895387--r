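## End-to-end pre/post cohort analysis: preprocessing, two-stage microstate
## analysis, network band energies, and the repeated-measures statistical
## layer, orchestrated deterministically from a single configuration.

#' Pipeline configuration
#'
#' All tunable parameters of [run_cohort()] in one validated, serializable
#' list. Any module seed is derived from the single `seed`.
#'
#' @param ms_band Microstate analysis band (Hz), default 2-20.
#' @param k Number of microstate classes, or `"auto"` for the
#'   meta-criterion.
#' @param n_restarts K-means restarts per fit.
#' @param epoch_s Epoch length for the network arm (s).
#' @param reject_uv Amplitude-rejection threshold (microvolts).
#' @param notch_hz Optional mains notch frequency (`NULL` to skip).
#' @param bands [band_definition()] for the network arm.
#' @param alpha Significance level of the statistical layer.
#' @param posthoc_family Post hoc family-size rule: Bonferroni `m` equals
#'   the number of levels compared pre vs post (4 classes, 12 transition
#'   pairs, 8 networks).
#' @param green_sigma Smoothness of the network covariance priors.
#' @param seed Master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(ms_band = c(2, 20), k = 4, n_restarts = 20,
                            epoch_s = 2, reject_uv = 100, notch_hz = NULL,
                            bands = band_definition(), alpha = 0.05,
                            posthoc_family = "levels", green_sigma = 0.6,
                            seed = 1L) {
  stop_if(!identical(k, "auto") && (!is.numeric(k) || k < 2),
          "k must be >= 2 or \"auto\"")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  structure(list(ms_band = ms_band, k = k, n_restarts = n_restarts,
                 epoch_s = epoch_s, reject_uv = reject_uv,
                 notch_hz = notch_hz, bands = bands, alpha = alpha,
                 posthoc_family = posthoc_family, green_sigma = green_sigma,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

ms_preproc <- function(rec, config) {
  if (!is.null(config$notch_hz)) rec <- notch_filter(rec, config$notch_hz)
  rec <- bandpass_filter(rec, config$ms_band[1], config$ms_band[2])
  rereference_average(rec)
}

transition_pair_names <- function(k = 4) {
  cls <- LETTERS[seq_len(k)]
  out <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j)
    out <- c(out, paste0(cls[i], ">", cls[j]), paste0(cls[j], ">", cls[i]))
  out
}

#' Run the full pre/post cohort analysis
#'
#' For every subject and condition: microstate preprocessing (band-pass and
#' average reference), GFP-peak extraction and subject-level polarity-
#' invariant k-means; then group maps pooled over all subjects and
#' conditions, backfitting, temporal parameters and transition fractions.
#' When the cohort carries a network arm, 2-s epochs are cut, amplitude-
#' rejected, and per-network band energies estimated by the empirical-Bayes
#' inversion. A repeated-measures ANOVA layer (time x class, time x pair,
#' and time x network per band) with Bonferroni-corrected paired post hocs
#' completes the run.
#'
#' @param cohort An [simulate_cohort()] cohort (or a compatible list of
#'   subjects with `pre` / `post` recordings).
#' @param config A [pipeline_config()].
#' @return Object of class `cohort_results` with elements `group_model`,
#'   `parameters` (arrays subjects x condition x class), `transitions`
#'   (subjects x condition x pair), `energies` (subjects x condition x
#'   network x band, if the network arm ran), `anova`, `posthoc`.
#' @export
run_cohort <- function(cohort, config = pipeline_config()) {
  subjects <- cohort$subjects
  ns <- length(subjects)
  stop_if(ns < 2, "need at least 2 subjects")
  conds <- c("pre", "post")
  seeds <- derive_seeds(config$seed, ns * 2 + 2)
  ## ---- microstate arm -------------------------------------------------
  recs <- list()
  models <- list()
  peaksets <- list()
  si <- 0
  for (s in seq_len(ns)) for (cn in conds) {
    si <- si + 1
    rec <- ms_preproc(subjects[[s]][[cn]]$ms, config)
    ts <- extract_gfp_peaks(rec)
    stop_if(attr(ts, "empty"),
            "microstate stage: no GFP peaks for subject %d %s", s, cn)
    key <- paste(s, cn)
    recs[[key]] <- rec
    peaksets[[key]] <- ts
    k_s <- if (identical(config$k, "auto"))
      as.integer(optimal_k_metacriterion(ts, n_restarts = config$n_restarts,
                                         seed = seeds[si]))
    else config$k
    models[[key]] <- microstate_fit(ts, k_s, n_restarts = config$n_restarts,
                                    seed = seeds[si])
  }
  k_group <- if (identical(config$k, "auto"))
    as.integer(round(stats::median(vapply(models, function(m) m$k, numeric(1)))))
  else config$k
  reference <- cohort$ledger$templates
  group_model <- group_maps_two_stage(models, k_group, reference = reference,
                                      n_restarts = config$n_restarts,
                                      seed = seeds[ns * 2 + 1])
  cls <- group_model$class_names
  pair_names <- transition_pair_names(k_group)
  params <- array(NA_real_, c(ns, 2, k_group, 4),
                  dimnames = list(NULL, conds, cls,
                                  c("duration_ms", "occurrence_per_s",
                                    "coverage", "gev")))
  trans <- array(NA_real_, c(ns, 2, length(pair_names)),
                 dimnames = list(NULL, conds, pair_names))
  for (s in seq_len(ns)) for (ci in 1:2) {
    key <- paste(s, conds[ci])
    seg <- backfit(recs[[key]], group_model)
    st <- microstate_stats(seg, recs[[key]])
    params[s, ci, , ] <- as.matrix(st[, c("duration_ms", "occurrence_per_s",
                                          "coverage", "gev")])
    tp <- transition_probabilities(seg)$probs
    trans[s, ci, ] <- vapply(pair_names, function(pn) {
      ij <- strsplit(pn, ">")[[1]]
      tp[ij[1], ij[2]]
    }, numeric(1))
  }
  ## ---- network arm ----------------------------------------------------
  energies <- NULL
  if (!is.null(subjects[[1]]$pre$net)) {
    lead <- cohort$lead; atlas <- cohort$atlas; bands <- cohort$bands
    priors <- mesh_green_prior(lead$mesh, atlas, sigma = config$green_sigma)
    nn <- length(atlas$names)
    energies <- array(NA_real_, c(ns, 2, nn, nrow(bands)),
                      dimnames = list(NULL, conds, atlas$names, bands$name))
    for (s in seq_len(ns)) for (ci in 1:2) {
      ep <- epoch_fixed_length(subjects[[s]][[conds[ci]]]$net, config$epoch_s)
      ep <- reject_artifacts_amplitude(ep, config$reject_uv)
      energies[s, ci, , ] <- band_energies(ep, lead, priors, bands)
    }
  }
  ## ---- statistical layer ----------------------------------------------
  anova <- list()
  posthoc <- list()
  for (pm in c("duration_ms", "occurrence_per_s", "coverage")) {
    anova[[pm]] <- rm_anova_two_way(params[, , , pm],
                                    factor_names = c("time", "class"))
    posthoc[[pm]] <- posthoc_paired(params[, , , pm], cls, config$alpha)
  }
  anova$transitions <- rm_anova_two_way(trans,
                                        factor_names = c("time", "pair"))
  posthoc$transitions <- posthoc_paired(trans, pair_names, config$alpha)
  if (!is.null(energies)) {
    for (b in dimnames(energies)[[4]]) {
      nm <- paste0("energy_", b)
      anova[[nm]] <- rm_anova_two_way(energies[, , , b],
                                      factor_names = c("time", "network"))
      posthoc[[nm]] <- posthoc_paired(energies[, , , b],
                                      dimnames(energies)[[3]], config$alpha)
    }
  }
  structure(list(group_model = group_model, subject_models = models,
                 parameters = params, transitions = trans,
                 energies = energies, anova = anova, posthoc = posthoc,
                 config = config),
            class = "cohort_results")
}

## paired pre/post t per level with Bonferroni over the levels
posthoc_paired <- function(arr, level_names, alpha) {
  m <- length(level_names)
  out <- data.frame(level = level_names, mean_pre = NA_real_,
                    mean_post = NA_real_, mean_diff = NA_real_, t = NA_real_,
                    df = NA_real_, p_raw = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    pre <- arr[, 1, i]; post <- arr[, 2, i]
    ok <- is.finite(pre) & is.finite(post)
    out$mean_pre[i] <- mean(pre[ok]); out$mean_post[i] <- mean(post[ok])
    if (sum(ok) >= 2 && stats::sd(post[ok] - pre[ok]) > 0) {
      tt <- paired_t(post[ok], pre[ok])
      out$mean_diff[i] <- tt["mean_diff"]; out$t[i] <- tt["t"]
      out$df[i] <- tt["df"]; out$p_raw[i] <- tt["p"]
    }
  }
  out$p_bonferroni <- bonferroni_adjust(ifelse(is.na(out$p_raw), 1,
                                               out$p_raw), m)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' @export
print.cohort_results <- function(x, ...) {
  ns <- dim(x$parameters)[1]
  cat(sprintf("<cohort_results> %d subjects, %d microstate classes%s\n",
              ns, dim(x$parameters)[3],
              if (is.null(x$energies)) ""
              else sprintf(", %d networks x %d bands",
                           dim(x$energies)[3], dim(x$energies)[4])))
  for (nm in names(x$anova)) {
    a <- x$anova[[nm]]
    i <- nrow(a)       # interaction row
    cat(sprintf("  %-18s interaction F(%.3f,%.3f) = %.3f, p = %.4f, eta2p = %.3f\n",
                nm, a$df1_corrected[i], a$df2_corrected[i], a$F[i], a$p[i],
                a$eta2p[i]))
  }
  invisible(x)
}

#' Write cohort result tables to CSV
#'
#' Emits per-subject parameter and transition tables, group prototypes, the
#' energy table (if present), ANOVA tables and post hoc tables, plus a JSON
#' manifest with the configuration.
#'
#' @param results A `cohort_results` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  flat <- function(arr) {
    d <- dimnames(arr)
    do.call(rbind, lapply(seq_len(dim(arr)[1]), function(s) {
      g <- expand.grid(condition = d[[2]], level = d[[3]],
                       stringsAsFactors = FALSE)
      g$subject <- s
      g$value <- as.vector(arr[s, , ])
      g
    }))
  }
  for (pm in dimnames(results$parameters)[[4]])
    wr(flat(results$parameters[, , , pm]), paste0("parameters_", pm))
  wr(flat(results$transitions), "transitions")
  if (!is.null(results$energies)) {
    d <- dimnames(results$energies)
    en <- do.call(rbind, lapply(seq_len(dim(results$energies)[1]), function(s) {
      g <- expand.grid(condition = d[[2]], network = d[[3]], band = d[[4]],
                       stringsAsFactors = FALSE)
      g$subject <- s
      g$value <- as.vector(results$energies[s, , , ])
      g
    }))
    wr(en, "network_band_energy")
  }
  proto <- as.data.frame(t(coef(results$group_model)))
  wr(proto, "group_prototypes")
  for (nm in names(results$anova))
    wr(as.data.frame(results$anova[[nm]]), paste0("anova_", nm))
  for (nm in names(results$posthoc))
    wr(results$posthoc[[nm]], paste0("posthoc_", nm))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = results$config[
    setdiff(names(results$config), "bands")],
    n_subjects = dim(results$parameters)[1]),
    mp, auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(c(paths, mp))
}

#' Generate a demonstration cohort and analyze it end to end
#'
#' Builds a small synthetic cohort with the default planted effects
#' (state C dwell up, state D coverage down, A-C switching up, B-D
#' switching down, visual beta2 up), runs [run_cohort()] and optionally
#' writes the result tables.
#'
#' @param out_dir Optional output directory for [write_cohort_results()].
#' @param seed Master seed.
#' @param n_subjects Cohort size.
#' @param ms_length_s Microstate-recording length (s).
#' @param net_length_s Network-recording length (s).
#' @param net_fs Network-recording sampling rate (Hz).
#' @param mesh_subdiv Icosphere subdivision of the source mesh.
#' @param n_restarts K-means restarts used by the pipeline.
#' @param lead,atlas Optional precomputed `leadfield` / `network_atlas`
#'   (rebuilt when `NULL`); passing them avoids repeating the forward model
#'   across repeated cohort simulations.
#' @return The `cohort_results`, invisibly when `out_dir` is given.
#' @export
synth_demo <- function(out_dir = NULL, seed = 1L, n_subjects = 20,
                       ms_length_s = 40, net_length_s = 16, net_fs = 125,
                       mesh_subdiv = 2, n_restarts = 6,
                       lead = NULL, atlas = NULL) {
  montage <- montage_1010()
  if (is.null(lead)) {
    mesh <- cortical_mesh(mesh_subdiv)
    lead <- build_sphere_leadfield(sphere_head_model(), montage, mesh)
  }
  if (is.null(atlas)) atlas <- synthetic_atlas(lead$mesh, 8)
  spec <- cohort_spec(
    n_subjects = n_subjects,
    effects = list(state_C_duration = 1.5, state_D_coverage = 0.8,
                   AC_transition = 1.5, BD_transition = 0.7,
                   visual_beta2 = 1.4),
    base_ms = msgen_spec(length_s = ms_length_s),
    base_net = netgen_spec(active_network = "visual", band_hz = c(20, 30),
                           length_s = net_length_s, fs_hz = net_fs),
    seed = seed)
  cohort <- simulate_cohort(spec, montage, lead = lead, atlas = atlas)
  res <- run_cohort(cohort, pipeline_config(n_restarts = n_restarts,
                                            seed = seed))
  if (!is.null(out_dir)) {
    write_cohort_results(res, out_dir)
    return(invisible(res))
  }
  res
}
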