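## Microstate analysis: global field power, GFP-peak topographies,
## polarity-invariant (modified) k-means, two-stage group maps, backfitting
## and the standard temporal parameters.

#' Global field power
#'
#' Spatial standard deviation of the scalp potential at each time point:
#' `sqrt(mean((v - mean(v))^2))` across channels.
#'
#' @param x A channel vector, a channels x samples matrix, or an
#'   [eeg_recording()].
#' @return Non-negative numeric vector, one value per sample.
#' @export
gfp <- function(x) {
  if (inherits(x, "eeg_recording")) x <- x$data
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  stop_if(nrow(x) < 2, "GFP needs at least 2 channels")
  cm <- colMeans(x)
  sqrt(colMeans(sweep(x, 2, cm)^2))
}

#' Absolute spatial correlation between two topographies
#'
#' Pearson correlation across channels after mean removal, in absolute
#' value: map polarity is ignored throughout the microstate pipeline.
#'
#' @param a,b Channel vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
spatial_correlation_abs <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  stop_if(na < 1e-300 || nb < 1e-300,
          "spatial correlation undefined for a zero-variance map")
  min(1, abs(sum(a * b)) / (na * nb))
}

#' Topographies at the local peaks of global field power
#'
#' Selects every sample whose GFP is a strict local maximum
#' (`GFP(t) > GFP(t-1)` and `GFP(t) > GFP(t+1)`) and returns the
#' mean-removed maps at those samples. Input should already be 2-20 Hz
#' filtered and average-referenced.
#'
#' @param rec An [eeg_recording()].
#' @return Object of class `topography_set`: `maps` (n_peaks x channels,
#'   zero-mean rows), `gfp_at_peak`, `source_times` (sample indices).
#'   When the GFP series has no strict local maximum, the set is empty and
#'   flagged with attribute `empty = TRUE`.
#' @export
extract_gfp_peaks <- function(rec) {
  g <- gfp(rec)
  pk <- gfp_peak_indices(g)
  maps <- t(rec$data[, pk, drop = FALSE])
  if (length(pk)) maps <- maps - rowMeans(maps)
  out <- structure(list(maps = maps, gfp_at_peak = g[pk], source_times = pk),
                   class = "topography_set")
  attr(out, "empty") <- length(pk) == 0
  out
}

gfp_peak_indices <- function(g) {
  n <- length(g)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[g[i] > g[i - 1] & g[i] > g[i + 1]]
}

#' @export
print.topography_set <- function(x, ...) {
  cat(sprintf("<topography_set> %d maps x %d channels\n",
              nrow(x$maps), ncol(x$maps)))
  invisible(x)
}

## normalize map rows to zero mean, unit norm
normalize_maps <- function(M) {
  M <- M - rowMeans(M)
  M / sqrt(rowSums(M^2) + 1e-300)
}

#' Fit microstate template maps by polarity-invariant k-means
#'
#' The modified (topographic) k-means: maps are assigned to the prototype
#' with the largest absolute spatial correlation, and each prototype is
#' updated to the dominant eigenvector of the cross-product matrix of its
#' assigned maps (the sign-invariant mean). The best of `n_restarts` random
#' initializations by global explained variance is returned. An emptied
#' cluster is re-seeded from the currently worst-fitted map.
#'
#' @param tset A `topography_set` from [extract_gfp_peaks()], or a plain
#'   n_maps x channels matrix.
#' @param k Number of microstate classes.
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer seed.
#' @param max_iter Iteration cap per restart.
#' @param tol Convergence tolerance on the GEV increase.
#' @param init Optional k x channels matrix used as one additional
#'   warm-start initialization (e.g. the maps of a smaller model plus extra
#'   seeds), guaranteeing the returned GEV is at least the warm start's.
#' @return Object of class `microstate_model`: `prototypes` (k x channels,
#'   zero-mean unit-norm rows), `k`, `gev_total`, `labels` (assignment of the
#'   input maps), `class_names`.
#' @seealso [backfit()], [microstate_stats()], [optimal_k_metacriterion()]
#' @export
microstate_fit <- function(tset, k, n_restarts = 50, seed = 1L,
                           max_iter = 100, tol = 1e-7, init = NULL) {
  X <- if (inherits(tset, "topography_set")) tset$maps else as.matrix(tset)
  w <- if (inherits(tset, "topography_set")) tset$gfp_at_peak
       else gfp(t(X))
  n <- nrow(X)
  stop_if(n < k, "need at least k maps (%d < %d)", n, k)
  Xn <- normalize_maps(X)
  best <- NULL
  seeds <- derive_seeds(seed, n_restarts)
  starts <- c(list(init)[!is.null(init)], vector("list", n_restarts))
  for (r in seq_along(starts)) {
    fit <- with_seed(seeds[((r - 1) %% n_restarts) + 1],
                     kmeans_once(Xn, w, k, max_iter, tol, starts[[r]]))
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }
  structure(list(k = k, prototypes = best$prototypes,
                 gev_total = best$gev, labels = best$labels,
                 class_names = LETTERS[seq_len(k)]),
            class = "microstate_model")
}

## one k-means run on normalized maps Xn with GFP weights w. Each iterate is
## scored as a full model (partition eigenvector prototypes + best
## assignment) and the best-scoring iterate is returned, so a warm start
## (P0, itself made of partition eigenvectors) can never be degraded.
kmeans_once <- function(Xn, w, k, max_iter, tol, P0 = NULL) {
  n <- nrow(Xn)
  P <- if (is.null(P0)) Xn[sample.int(n, k), , drop = FALSE]
       else normalize_maps(P0)
  w2 <- w^2
  score <- function(P) {
    S <- abs(Xn %*% t(P))
    labels <- max.col(S, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(labels == j)) {             # re-seed from worst-fitted map
        worst <- which.min(S[cbind(seq_len(n), labels)])
        labels[worst] <- j
      }
    }
    cc <- abs(rowSums(Xn * P[labels, , drop = FALSE]))
    list(labels = labels, gev = sum(w2 * cc^2) / sum(w2))
  }
  best <- if (is.null(P0)) list(gev = -Inf) else c(list(prototypes = P),
                                                   score(P))
  cur <- score(P)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k))
      P[j, ] <- dominant_eigvec(crossprod(Xn[cur$labels == j, , drop = FALSE]))
    nxt <- score(P)
    if (nxt$gev > best$gev)
      best <- c(list(prototypes = P), nxt)
    if (nxt$gev - cur$gev < tol) break
    cur <- nxt
  }
  best$prototypes <- normalize_maps(best$prototypes)
  best
}

dominant_eigvec <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d (%s), total GEV = %.3f\n",
              x$k, paste(x$class_names, collapse = ""), x$gev_total))
  invisible(x)
}

#' @export
summary.microstate_model <- function(object, ...) {
  cat(sprintf("Microstate model with %d classes (%s)\n", object$k,
              paste(object$class_names, collapse = ", ")))
  cat(sprintf("Global explained variance of the fitted maps: %.3f\n",
              object$gev_total))
  if (!is.null(object$labels))
    print(table(class = factor(object$labels,
                               labels = object$class_names[sort(unique(object$labels))])))
  invisible(object)
}

#' @export
coef.microstate_model <- function(object, ...) {
  p <- object$prototypes
  rownames(p) <- object$class_names
  p
}

#' @export
plot.microstate_model <- function(x, ...) {
  graphics::matplot(t(x$prototypes), type = "l", lty = 1,
                    xlab = "channel", ylab = "normalized potential", ...)
  graphics::legend("topright", legend = x$class_names, lty = 1,
                   col = seq_len(x$k), bty = "n")
  invisible(x)
}

#' Two-stage group microstate maps
#'
#' Pools the subject-level prototypes of all models and re-runs the
#' polarity-invariant k-means on the pooled set, then orders the output
#' classes by best match to reference class topographies when given.
#'
#' @param models List of subject `microstate_model`s (length >= 1).
#' @param k_group Number of group classes.
#' @param reference Optional k x channels matrix of canonical class maps
#'   used only to order and name the output classes A, B, C, D, ...
#' @param n_restarts,seed Passed to [microstate_fit()].
#' @return A group `microstate_model`.
#' @export
group_maps_two_stage <- function(models, k_group, reference = NULL,
                                 n_restarts = 50, seed = 1L) {
  pooled <- do.call(rbind, lapply(models, function(m) m$prototypes))
  stop_if(nrow(pooled) < k_group,
          "k_group (%d) exceeds the %d pooled prototypes", k_group, nrow(pooled))
  gm <- microstate_fit(pooled, k_group, n_restarts = n_restarts, seed = seed)
  if (!is.null(reference)) {
    gm <- order_classes(gm, reference)
  }
  gm
}

## greedy one-to-one matching of prototypes to reference maps by |corr|
order_classes <- function(model, reference) {
  S <- map_corr_matrix(model$prototypes, reference)
  k <- model$k; kr <- nrow(reference)
  ord <- integer(0); used <- logical(k)
  for (j in seq_len(min(k, kr))) {
    cand <- which(!used)
    pick <- cand[which.max(S[cand, j])]
    ord <- c(ord, pick); used[pick] <- TRUE
  }
  ord <- c(ord, which(!used))
  model$prototypes <- model$prototypes[ord, , drop = FALSE]
  if (!is.null(model$labels)) model$labels <- match(model$labels, ord)
  model
}

#' Backfit template maps to a recording
#'
#' Labels every GFP-peak sample with the prototype of greatest absolute
#' spatial correlation; all other samples inherit the label of the nearest
#' peak in time (ties to the earlier peak), including samples before the
#' first and after the last peak.
#'
#' @param rec An [eeg_recording()] (2-20 Hz filtered, average-referenced).
#' @param model A `microstate_model`.
#' @return Object of class `segmentation`: per-sample integer `labels`,
#'   `corr_series` (absolute correlation of each sample to its assigned
#'   prototype), `fs_hz`, `peaks`. Empty (flagged) when the recording has no
#'   GFP peaks.
#' @export
backfit <- function(rec, model) {
  stop_if(ncol(model$prototypes) != n_channels(rec),
          "model channels (%d) do not match the recording (%d)",
          ncol(model$prototypes), n_channels(rec))
  ts <- extract_gfp_peaks(rec)
  n <- n_samples(rec)
  if (attr(ts, "empty")) {
    out <- structure(list(labels = integer(0), corr_series = numeric(0),
                          fs_hz = rec$fs_hz, peaks = integer(0), k = model$k),
                     class = "segmentation")
    attr(out, "empty") <- TRUE
    return(out)
  }
  Pk <- normalize_maps(ts$maps)
  S <- abs(Pk %*% t(model$prototypes))
  peak_lab <- max.col(S, ties.method = "first")
  ## nearest-peak interpolation: boundaries at midpoints, ties -> earlier
  pk <- ts$source_times
  if (length(pk) == 1) {
    labels <- rep(peak_lab, n)
  } else {
    mid <- floor((pk[-length(pk)] + pk[-1]) / 2)
    labels <- rep(peak_lab, times = diff(c(0, mid, n)))
  }
  X <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
  Xn <- t(X) / sqrt(colSums(X^2) + 1e-300)
  corr <- abs(rowSums(Xn * model$prototypes[labels, , drop = FALSE]))
  structure(list(labels = labels, corr_series = pmin(corr, 1),
                 fs_hz = rec$fs_hz, peaks = pk, k = model$k),
            class = "segmentation")
}

#' @export
predict.microstate_model <- function(object, rec, ...) backfit(rec, object)

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d samples @ %g Hz, %d states, %d GFP peaks\n",
              length(x$labels), x$fs_hz, x$k, length(x$peaks)))
  invisible(x)
}

#' Temporal microstate parameters
#'
#' Per state: mean duration of uninterrupted runs (ms), occurrences per
#' second, coverage (fraction of samples), and the global explained variance
#' attributable to that state, `sum_t GFP(t)^2 corr(t)^2 / sum_t GFP(t)^2`
#' over its samples. States never observed get `NA` duration and zero
#' occurrence/coverage/GEV.
#'
#' @param seg A [backfit()] segmentation.
#' @param rec The [eeg_recording()] the segmentation came from.
#' @return Data frame with one row per state: `state`, `duration_ms`,
#'   `occurrence_per_s`, `coverage`, `gev`.
#' @export
microstate_stats <- function(seg, rec) {
  stop_if(length(seg$labels) == 0, "empty segmentation")
  k <- seg$k
  runs <- rle(seg$labels)
  total_s <- length(seg$labels) / seg$fs_hz
  g2 <- gfp(rec)^2
  gc2 <- g2 * seg$corr_series^2
  out <- data.frame(state = LETTERS[seq_len(k)],
                    duration_ms = NA_real_, occurrence_per_s = 0,
                    coverage = 0, gev = 0, stringsAsFactors = FALSE)
  for (s in seq_len(k)) {
    rl <- runs$lengths[runs$values == s]
    if (length(rl)) {
      out$duration_ms[s] <- mean(rl) * 1000 / seg$fs_hz
      out$occurrence_per_s[s] <- length(rl) / total_s
      out$coverage[s] <- sum(rl) / length(seg$labels)
      out$gev[s] <- sum(gc2[seg$labels == s]) / sum(g2)
    }
  }
  out
}

#' Microstate transition probabilities
#'
#' Counts run-boundary switches `i -> j` (`i != j`) and normalizes by the
#' total number of switches, per the standard definition: the fraction of
#' all inter-state switches going from state i to state j.
#'
#' @param seg A [backfit()] segmentation.
#' @return List of class `transition_matrix` with integer `counts` and
#'   `probs` (both K x K, zero diagonal; `probs` sums to 1). A segmentation
#'   with a single run yields zero counts and is flagged with attribute
#'   `no_transitions`.
#' @export
transition_probabilities <- function(seg) {
  k <- seg$k
  runs <- rle(seg$labels)$values
  counts <- matrix(0L, k, k,
                   dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  if (length(runs) >= 2) {
    from <- runs[-length(runs)]; to <- runs[-1]
    counts[] <- tabulate((to - 1L) * k + from, nbins = k * k)
  }
  tot <- sum(counts)
  probs <- if (tot > 0) counts / tot else counts * 0
  out <- structure(list(counts = counts, probs = probs),
                   class = "transition_matrix")
  attr(out, "no_transitions") <- tot == 0
  out
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> switch fractions:\n")
  print(round(x$probs, 3))
  invisible(x)
}
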