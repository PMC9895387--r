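## Choice of the number of microstate classes: a battery of cluster-validity
## criteria evaluated under the polarity-invariant dissimilarity
## d(a, b) = 1 - |corr(a, b)|, combined by a median-vote meta-criterion.

#' Optimal number of microstates by a meta-criterion
#'
#' Fits polarity-invariant k-means over `k_range` and scores each k with a
#' battery of cluster-validity criteria (by default seven: Krzanowski-Lai,
#' silhouette, Davies-Bouldin (inverted), point-biserial, Dunn,
#' Calinski-Harabasz and a cross-validation criterion), all computed under
#' the dissimilarity `1 - |spatial correlation|`. Each criterion votes for
#' its best k; the meta-criterion returns the median vote, rounding ties to
#' the smaller k.
#'
#' @param tset A `topography_set` or n_maps x channels matrix.
#' @param k_range Candidate numbers of classes (default `2:8`).
#' @param criteria Character subset of
#'   `c("kl", "silhouette", "db", "pointbiserial", "dunn", "ch", "cv")`.
#' @param n_restarts Restarts per k for the underlying fits.
#' @param seed Integer seed (fits and pairwise-criteria subsampling).
#' @param subsample Cap on the number of maps used by the pairwise criteria
#'   (silhouette, point-biserial, Dunn).
#' @return The selected k, with the per-criterion votes as attribute
#'   `"votes"` and the fitted models as attribute `"models"`.
#' @export
optimal_k_metacriterion <- function(tset, k_range = 2:8,
                                    criteria = c("kl", "silhouette", "db",
                                                 "pointbiserial", "dunn",
                                                 "ch", "cv"),
                                    n_restarts = 20, seed = 1L,
                                    subsample = 400) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  X <- if (inherits(tset, "topography_set")) tset$maps else as.matrix(tset)
  n <- nrow(X); C <- ncol(X)
  stop_if(min(k_range) < 2 || max(k_range) > n,
          "k_range must lie within [2, n_maps]")
  Xn <- normalize_maps(X)
  ## fit k-range (extended by one on each side for Krzanowski-Lai), nesting
  ## each fit's warm start in the previous solution
  ks <- max(2, min(k_range) - 1):min(n, max(k_range) + 1)
  fits <- vector("list", length(ks)); names(fits) <- ks
  prev <- NULL
  for (i in seq_along(ks)) {
    init <- if (!is.null(prev))
      rbind(prev$prototypes,
            Xn[with_seed(seed + i, sample.int(n, ks[i] - prev$k)), ,
               drop = FALSE])
    fits[[i]] <- microstate_fit(tset, ks[i], n_restarts = n_restarts,
                                seed = seed + i, init = init)
    prev <- fits[[i]]
  }
  ## within-cluster unexplained variance W(k) = sum_t (1 - corr_t^2)
  Wk <- vapply(fits, function(f) {
    cc <- abs(rowSums(Xn * f$prototypes[f$labels, , drop = FALSE]))
    sum(1 - cc^2)
  }, numeric(1))
  ## subsampled pairwise dissimilarities for silhouette/point-biserial/Dunn
  sub <- with_seed(seed, sample.int(n, min(subsample, n)))
  Dsub <- 1 - map_corr_matrix(Xn[sub, , drop = FALSE], Xn[sub, , drop = FALSE])
  diag(Dsub) <- 0

  in_range <- as.character(k_range)
  score <- function(fun) {
    v <- vapply(in_range, function(kc) fun(fits[[kc]], Wk[kc]), numeric(1))
    names(v) <- in_range
    v
  }
  votes <- c()
  for (cr in criteria) {
    v <- switch(cr,
      kl = {
        kl <- vapply(k_range, function(k) {
          km1 <- as.character(k - 1); kp1 <- as.character(k + 1); kc <- as.character(k)
          if (!(km1 %in% names(Wk)) || !(kp1 %in% names(Wk))) return(NA_real_)
          diff1 <- (k - 1)^(2 / C) * Wk[km1] - k^(2 / C) * Wk[kc]
          diff2 <- k^(2 / C) * Wk[kc] - (k + 1)^(2 / C) * Wk[kp1]
          if (abs(diff2) < 1e-12) return(NA_real_)
          abs(diff1 / diff2)
        }, numeric(1))
        names(kl) <- in_range
        kl
      },
      silhouette = score(function(f, w) mean_silhouette(Dsub, f$labels[sub])),
      db = score(function(f, w) -davies_bouldin(Xn, f)),
      pointbiserial = score(function(f, w) point_biserial(Dsub, f$labels[sub])),
      dunn = score(function(f, w) dunn_index(Dsub, f$labels[sub])),
      ch = {
        Tot <- T0(Xn)
        score(function(f, w) ((Tot - w) / (f$k - 1)) / (w / max(n - f$k, 1)))
      },
      cv = score(function(f, w) -(w / (n * (C - 1))) *
                   ((C - 1) / max(C - 1 - f$k, 1))^2)
    )
    if (all(!is.finite(v))) next
    votes[cr] <- k_range[which.max(replace(v, !is.finite(v), -Inf))]
  }
  stop_if(length(votes) == 0, "all cluster-validity criteria were undefined")
  structure(median_vote(votes), votes = votes,
            models = fits[in_range])
}

## lower median of the criterion votes: ties resolve to the smaller k
median_vote <- function(votes) {
  sv <- sort(votes)
  as.integer(unname(sv[ceiling(length(sv) / 2)]))
}

## total unexplained variance with a single polarity-invariant mean map
T0 <- function(Xn) {
  p <- dominant_eigvec(crossprod(Xn))
  sum(1 - drop(Xn %*% p)^2)
}

mean_silhouette <- function(D, lab) {
  k <- length(unique(lab))
  if (k < 2) return(NA_real_)
  n <- length(lab)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- lab == lab[i]; same[i] <- FALSE
    a <- if (any(same)) mean(D[i, same]) else 0
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(D[i, lab == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b, 1e-12)
  }
  mean(s)
}

davies_bouldin <- function(Xn, f) {
  k <- f$k
  scat <- vapply(seq_len(k), function(j) {
    idx <- f$labels == j
    if (!any(idx)) return(NA_real_)
    mean(1 - abs(Xn[idx, , drop = FALSE] %*% f$prototypes[j, ]))
  }, numeric(1))
  M <- 1 - map_corr_matrix(f$prototypes, f$prototypes)
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (scat[i] + scat[j]) / max(M[i, j], 1e-12),
               numeric(1)))
  }, numeric(1))
  mean(r, na.rm = TRUE)
}

point_biserial <- function(D, lab) {
  n <- length(lab)
  ut <- upper.tri(D)
  d <- D[ut]
  same <- (outer(lab, lab, "=="))[ut]
  if (all(same) || !any(same)) return(NA_real_)
  -stats::cor(d, as.numeric(same))   # within-pairs smaller => positive score
}

dunn_index <- function(D, lab) {
  groups <- unique(lab)
  if (length(groups) < 2) return(NA_real_)
  diam <- max(vapply(groups, function(g) {
    idx <- lab == g
    if (sum(idx) < 2) 0 else max(D[idx, idx])
  }, numeric(1)))
  sep <- Inf
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i < j) sep <- min(sep, min(D[lab == groups[i], lab == groups[j]]))
  }
  sep / max(diam, 1e-12)
}
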