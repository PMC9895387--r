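## Network rhythm-energy estimation: covariance priors from the Green
## function of the mesh adjacency, ReML (parametric empirical Bayes)
## estimation of the prior weights, and per-network per-band mean squared
## current density.

#' Network covariance priors from the mesh Green function
#'
#' Computes `G = expm(sigma * W)` with `W` the row-normalized mesh adjacency
#' (a smoothing Green function: non-negative, local coherence falling off
#' with graph distance), then builds one covariance component per network by
#' restricting G's rows and columns to that network's vertices, zeroing all
#' other entries, symmetrizing and flooring negative eigenvalues at zero.
#'
#' @param mesh A [cortical_mesh()].
#' @param atlas A [synthetic_atlas()] (or compatible vertex labelling).
#' @param sigma Smoothness parameter (`sigma = 0` gives identity priors).
#' @return Object of class `covariance_priors`: list `priors` of V x V
#'   matrices (one per network), plus the atlas.
#' @export
mesh_green_prior <- function(mesh, atlas, sigma = 0.6) {
  stop_if(sigma < 0, "sigma must be >= 0")
  V <- nrow(mesh$vertices)
  stop_if(length(atlas$labels) != V, "atlas does not match the mesh")
  A <- as.matrix(mesh$adjacency)
  deg <- pmax(rowSums(A), 1)
  G <- as.matrix(Matrix::expm(Matrix::Matrix(sigma * A / deg)))
  nets <- seq_along(atlas$names)
  priors <- lapply(nets, function(i) {
    idx <- which(atlas$labels == i)
    Vi <- matrix(0, V, V)
    B <- (G[idx, idx, drop = FALSE] + t(G[idx, idx, drop = FALSE])) / 2
    e <- eigen(B, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    Vi[idx, idx] <- e$vectors %*% (ev * t(e$vectors))
    Vi
  })
  names(priors) <- atlas$names
  structure(list(priors = priors, atlas = atlas), class = "covariance_priors")
}

#' @export
print.covariance_priors <- function(x, ...) {
  cat(sprintf("<covariance_priors> %d network components on %d vertices\n",
              length(x$priors), nrow(x$priors[[1]])))
  invisible(x)
}

#' ReML estimation of prior covariance weights
#'
#' Models the sensor covariance as
#' `C = exp(l0) I + sum_i exp(l_i) L V_i L'` and maximizes the restricted
#' log likelihood (free energy) over the log weights `l` by Fisher scoring
#' with step halving, so the recorded evidence trajectory is non-decreasing.
#' Returns the hyperparameters and the posterior-mean source operator
#' `M = (sum_i exp(l_i) V_i) L' C^-1`.
#'
#' @param sensor_cov Electrodes x electrodes sample covariance (PSD).
#' @param lead A `leadfield` (or plain gain matrix).
#' @param priors A `covariance_priors` object (or list of V x V matrices).
#' @param n_samples Effective number of samples behind `sensor_cov`.
#' @param max_iter Iteration cap (default 128).
#' @param tol Convergence tolerance on the evidence change per effective
#'   sample (default 1e-4).
#' @param lambda_floor Lower bound on the log weights, relative to the log
#'   of the mean sensor variance (default -32), keeping the fit
#'   scale-equivariant.
#' @return Object of class `reml_fit`: `lambda` (log weights, noise first),
#'   `evidence` (per-iteration free energy), `operator` (vertices x
#'   electrodes posterior-mean operator), `converged`, `model_cov`.
#' @export
reml_estimate <- function(sensor_cov, lead, priors, n_samples = 100,
                          max_iter = 128, tol = 1e-4, lambda_floor = -32) {
  L <- if (inherits(lead, "leadfield")) lead$gain else as.matrix(lead)
  Vs <- if (inherits(priors, "covariance_priors")) priors$priors else priors
  E <- nrow(L)
  stop_if(nrow(sensor_cov) != E || ncol(sensor_cov) != E,
          "sensor_cov must be %d x %d", E, E)
  S <- (sensor_cov + t(sensor_cov)) / 2
  ## sensor-space projections of the priors; scale-normalized so the
  ## hyperparameters are comparable
  LVL <- lapply(Vs, function(Vi) L %*% Vi %*% t(L))
  qscale <- vapply(LVL, function(M) max(mean(diag(M)), 1e-300), numeric(1))
  Q <- c(list(diag(E)), Map(`/`, LVL, qscale))
  nq <- length(Q)
  scl <- mean(diag(S))
  if (scl <= 0) {                        # degenerate zero-signal input
    return(structure(list(lambda = rep(lambda_floor, nq), evidence = 0,
                          operator = matrix(0, ncol(L), nrow(L)),
                          converged = TRUE, model_cov = diag(E),
                          prior_names = names(Vs), degenerate = TRUE),
                     class = "reml_fit"))
  }
  ## the floor is relative to the data scale, preserving the c^2 scale
  ## equivariance of the energy estimates
  lambda_floor <- log(scl) + lambda_floor
  lam <- rep(log(scl / 2), nq)
  N <- n_samples
  free_energy <- function(lam) {
    C <- Reduce(`+`, Map(function(h, q) h * q, exp(lam), Q))
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(list(F = -Inf))
    iC <- chol2inv(ch)
    ld <- 2 * sum(log(diag(ch)))
    list(F = -N / 2 * (ld + sum(iC * S)), C = C, iC = iC)
  }
  cur <- free_energy(lam)
  evid <- cur$F
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iC <- cur$iC
    iCQ <- lapply(Q, function(q) iC %*% q)
    R <- iC %*% S %*% iC
    g <- vapply(seq_len(nq), function(k)
      -N / 2 * (sum(diag(iCQ[[k]])) - sum(R * Q[[k]])) * exp(lam[k]),
      numeric(1))
    H <- matrix(0, nq, nq)
    for (k in seq_len(nq)) for (l in k:nq) {
      H[k, l] <- H[l, k] <-
        N / 2 * sum(iCQ[[k]] * t(iCQ[[l]])) * exp(lam[k]) * exp(lam[l])
    }
    step <- tryCatch(solve(H + diag(nq) * max(diag(H)) * 1e-8, g),
                     error = function(e) g / max(diag(H), 1))
    ok <- FALSE
    for (half in 0:8) {                    # step halving keeps F monotone
      cand <- pmax(lam + step / 2^half, lambda_floor)
      fe <- free_energy(cand)
      if (fe$F >= cur$F - 1e-10) { ok <- TRUE; break }
    }
    if (!ok) break
    ## evidence *differences* are invariant under data rescaling, so this
    ## criterion keeps the whole fit scale-equivariant
    dF <- abs(fe$F - cur$F)
    lam <- cand; cur <- fe
    evid <- c(evid, fe$F)
    if (is.finite(dF) && dF < tol * max(N, 1)) { converged <- TRUE; break }
  }
  ## undo the sensor-space scale normalization applied to Q
  Rsum <- Reduce(`+`, Map(function(h, Vi, s) h * Vi / s,
                          exp(lam[-1]), Vs, qscale))
  operator <- Rsum %*% t(L) %*% cur$iC
  structure(list(lambda = lam, evidence = evid, operator = operator,
                 converged = converged, model_cov = cur$C,
                 prior_names = names(Vs)),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> %d components, evidence %.4g (%s, %d iterations)\n",
              length(x$lambda), x$evidence[length(x$evidence)],
              if (x$converged) "converged" else "not converged",
              length(x$evidence) - 1))
  invisible(x)
}

#' Standard resting-EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha1 8-10.5, alpha2 10.5-13, beta1 13-20,
#' beta2 20-30, gamma 30-45 Hz: conventional splits of a 0.5-45 Hz analysis
#' band.
#'
#' @param bands Optional data frame with columns `name`, `low_hz`, `high_hz`
#'   to override the default.
#' @return Data frame of class `band_definition`.
#' @export
band_definition <- function(bands = NULL) {
  if (is.null(bands))
    bands <- data.frame(
      name = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "gamma"),
      low_hz = c(0.5, 4, 8, 10.5, 13, 20, 30),
      high_hz = c(4, 8, 10.5, 13, 20, 30, 45),
      stringsAsFactors = FALSE)
  stop_if(any(bands$low_hz >= bands$high_hz), "band edges must increase")
  stop_if(any(diff(bands$low_hz) <= 0) || any(bands$high_hz[-nrow(bands)] >
                                                bands$low_hz[-1] + 1e-9),
          "bands must be ordered and non-overlapping")
  class(bands) <- c("band_definition", "data.frame")
  bands
}

#' Per-network, per-band mean current-density energy
#'
#' Estimates one posterior source operator by ReML from the broadband
#' epoch-averaged sensor covariance, then, for each frequency band,
#' band-passes the sensor epochs, applies the operator, and averages the
#' squared current density over time, over each network's vertices, and
#' over epochs.
#'
#' @param ep An [eeg_epochs()] object (kept epochs are used).
#' @param lead A `leadfield`.
#' @param priors A `covariance_priors`.
#' @param bands A [band_definition()].
#' @param n_samples Effective sample count passed to [reml_estimate()].
#' @param ... Further arguments to [reml_estimate()].
#' @return Networks x bands matrix of mean squared current density
#'   (arbitrary units), with the `reml_fit` as attribute `"fit"` and
#'   `epochs_used` as an attribute.
#' @export
band_energies <- function(ep, lead, priors, bands = band_definition(),
                          n_samples = NULL, ...) {
  eps <- kept_epochs(ep)
  stop_if(length(eps) < 1, "no kept epochs")
  fs <- ep$fs_hz
  stop_if(any(bands$high_hz >= fs / 2),
          "band edges must lie below fs/2 = %g Hz", fs / 2)
  E <- nrow(eps[[1]])
  S <- matrix(0, E, E)
  nt <- 0
  for (x in eps) { S <- S + tcrossprod(x); nt <- nt + ncol(x) }
  S <- S / nt
  if (is.null(n_samples)) n_samples <- nt
  fit <- reml_estimate(S, lead, priors, n_samples = n_samples, ...)
  atlas <- priors$atlas
  nets <- seq_along(atlas$names)
  energy <- matrix(0, length(nets), nrow(bands),
                   dimnames = list(atlas$names, bands$name))
  long <- do.call(cbind, eps)              # filter epochs jointly per band
  for (b in seq_len(nrow(bands))) {
    nt_b <- fir_ntaps(max(0.25 * bands$low_hz[b], 0.5), fs)
    nt_b <- min(nt_b, 2 * ncol(long) - 1)
    if (nt_b %% 2 == 0) nt_b <- nt_b - 1
    h <- signal::fir1(nt_b - 1, c(bands$low_hz[b], bands$high_hz[b]) / (fs / 2),
                      type = "pass")
    Xb <- fir_apply(long, h)
    J <- fit$operator %*% Xb
    msq <- rowMeans(J^2)
    energy[, b] <- vapply(nets, function(i)
      mean(msq[atlas$labels == i]), numeric(1))
  }
  attr(energy, "fit") <- fit
  attr(energy, "epochs_used") <- length(eps)
  energy
}
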