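## EEG forward modelling on concentric spherical conductors: the analytic
## homogeneous-sphere solution (closed form) and the three-shell Legendre
## series solved per harmonic with radius-normalized layer coefficients.

#' Three-shell spherical head model
#'
#' Concentric conducting spheres for brain, skull and scalp. Radii are
#' normalized to an outer (scalp) radius of 1; defaults are the standard
#' 0.87 / 0.92 / 1.0 geometry with conductivities 0.33 / 0.0042 / 0.33 S/m.
#'
#' @param radii Increasing positive radii of brain, skull, scalp surfaces.
#' @param conductivities Positive conductivities of the three layers (S/m).
#' @param n_terms Truncation order of the Legendre series.
#' @return An object of class `sphere_head_model`.
#' @export
sphere_head_model <- function(radii = c(0.87, 0.92, 1.0),
                              conductivities = c(0.33, 0.0042, 0.33),
                              n_terms = 100) {
  stop_if(length(radii) != 3 || any(diff(radii) <= 0) || radii[1] <= 0,
          "radii must be 3 increasing positive numbers")
  stop_if(length(conductivities) != 3 || any(conductivities <= 0),
          "conductivities must be 3 positive numbers")
  stop_if(n_terms < 1, "n_terms must be >= 1")
  structure(list(radii = radii, conductivities = conductivities,
                 n_terms = as.integer(n_terms)),
            class = "sphere_head_model")
}

#' Closed-form lead field for a homogeneous conducting sphere
#'
#' Analytic surface potential of current dipoles inside a homogeneous sphere
#' (no skull layer), obtained by summing the Legendre series in closed form.
#' Serves as the exact reference solution for the layered series solver and
#' as a generator of realistic dipolar scalp maps.
#'
#' @param electrodes E x 3 matrix of positions on the sphere surface.
#' @param positions D x 3 matrix of dipole positions strictly inside.
#' @param moments D x 3 matrix of dipole moments.
#' @param sigma Conductivity (S/m).
#' @param radius Sphere radius (defaults to the norm of the first electrode).
#' @return E x D matrix of potentials (not re-referenced).
#' @export
leadfield_homogeneous <- function(electrodes, positions, moments,
                                  sigma = 0.33, radius = NULL) {
  electrodes <- as.matrix(electrodes); positions <- as.matrix(positions)
  moments <- as.matrix(moments)
  if (is.null(radius)) radius <- sqrt(sum(electrodes[1, ]^2))
  R <- radius
  E <- nrow(electrodes); D <- nrow(positions)
  out <- matrix(0, E, D)
  rh <- electrodes / R
  for (j in seq_len(D)) {
    a <- positions[j, ]; q <- moments[j, ]
    av <- sqrt(sum(a^2))
    stop_if(av >= R, "dipole %d lies outside the sphere", j)
    if (av < 1e-12) { # central dipole: use a tiny offset along the moment
      a <- q / max(sqrt(sum(q^2)), 1e-12) * 1e-6 * R
      av <- sqrt(sum(a^2))
    }
    ah <- a / av
    x <- av / R
    cc <- drop(rh %*% ah)
    d <- sqrt(rowSums(sweep(electrodes, 2, a)^2))
    h <- d / R
    t1 <- 2 * drop(sweep(electrodes, 2, a) %*% q) / d^3
    t2 <- (sum(q * ah) * (1 - h) / (x * h) +
             drop(rh %*% q - cc * sum(q * ah)) * (1 + h) /
             (h * (1 - x * cc + h))) / R^2
    out[, j] <- (t1 + t2) / (4 * pi * sigma)
  }
  out
}

## Per-harmonic surface response of the three-shell model for a unit
## r^-(n+1) source harmonic in the inner layer. Layer coefficients are
## normalized by their interface radius to keep the 5x5 systems
## well-conditioned at high order.
shell_surface_factors <- function(head) {
  r1 <- head$radii[1]; r2 <- head$radii[2]; R <- head$radii[3]
  s1 <- head$conductivities[1]; s2 <- head$conductivities[2]
  s3 <- head$conductivities[3]
  N <- head$n_terms
  f <- numeric(N)
  for (n in seq_len(N)) {
    k12 <- (r1 / r2)^n; k12i <- (r1 / r2)^-(n + 1)
    k23 <- (r2 / R)^n;  k23i <- (r2 / R)^-(n + 1)
    M <- matrix(0, 5, 5); rhs <- numeric(5)
    ## V1 = (r/r1)^-(n+1) + A1 (r/r1)^n ; V2 = A2 (r/r2)^n + B2 (r/r2)^-(n+1)
    ## V3 = A3 (r/R)^n + B3 (r/R)^-(n+1); unknowns (A1, A2, B2, A3, B3)
    M[1, ] <- c(1, -k12, -k12i, 0, 0); rhs[1] <- -1
    M[2, ] <- c(s1 * n / r1, -s2 * n * k12 / r1, s2 * (n + 1) * k12i / r1,
                0, 0)
    rhs[2] <- s1 * (n + 1) / r1
    M[3, ] <- c(0, 1, 1, -k23, -k23i)
    M[4, ] <- c(0, s2 * n / r2, -s2 * (n + 1) / r2,
                -s3 * n * k23 / r2, s3 * (n + 1) * k23i / r2)
    M[5, ] <- c(0, 0, 0, n / R, -(n + 1) / R)
    x <- solve(M, rhs)
    f[n] <- (x[4] + x[5]) * r1^-(n + 1)
  }
  f
}

#' Three-shell spherical lead field
#'
#' Potential of one unit dipole per mesh vertex (oriented along the vertex
#' normal) at each electrode, via the Legendre-series solution for a dipole
#' inside three concentric conducting shells, truncated at
#' `head$n_terms`. Columns are re-referenced to the common average, so each
#' column sums to zero.
#'
#' @param head A [sphere_head_model()].
#' @param montage Electrode montage data frame (positions are rescaled onto
#'   the outer shell).
#' @param mesh A [cortical_mesh()]; vertices must lie strictly inside the
#'   innermost shell.
#' @return List of class `leadfield` with `gain` (electrodes x vertices) and
#'   the inputs used.
#' @export
build_sphere_leadfield <- function(head, montage, mesh) {
  el <- as.matrix(montage[, c("x", "y", "z")])
  el <- el / sqrt(rowSums(el^2)) * head$radii[3]
  vr <- sqrt(rowSums(mesh$vertices^2))
  stop_if(any(vr >= head$radii[1]),
          "%d mesh vertices lie on or outside the innermost shell",
          sum(vr >= head$radii[1]))
  ratio <- max(vr) / head$radii[3]
  tail_mag <- ratio^head$n_terms * head$n_terms
  if (tail_mag > 1e-4)
    warning(sprintf(paste0("series tail ~%.1e at n_terms=%d for vertices at ",
                           "%.0f%% of the outer radius; increase n_terms"),
                    tail_mag, head$n_terms, 100 * ratio))
  f <- shell_surface_factors(head)
  R <- head$radii[3]; s1 <- head$conductivities[1]
  rh <- el / R
  av <- vr
  ah <- mesh$vertices / av
  nv <- mesh$normals
  CC <- rh %*% t(ah)                       # E x V: cos(angle)
  mr <- rowSums(nv * ah)                   # V: radial moment component
  NR <- rh %*% t(nv)                       # E x V: normal . electrode dir
  TE <- NR - sweep(CC, 2, mr, `*`)         # E x V: tangential term
  E <- nrow(el); V <- nrow(mesh$vertices)
  G <- matrix(0, E, V)
  P0 <- matrix(1, E, V); P1 <- CC
  dP0 <- matrix(0, E, V); dP1 <- matrix(1, E, V)
  xpow <- rep(1, V)                        # av^(n-1)
  for (n in seq_len(head$n_terms)) {
    if (n == 1) { Pn <- P1; dPn <- dP1 } else {
      Pn <- ((2 * n - 1) * CC * P1 - (n - 1) * P0) / n
      dPn <- ((2 * n - 1) * (P1 + CC * dP1) - (n - 1) * dP0) / n
      P0 <- P1; P1 <- Pn; dP0 <- dP1; dP1 <- dPn
    }
    Sn <- sweep(Pn, 2, n * mr * xpow, `*`) + sweep(dPn, 2, xpow, `*`) * TE
    G <- G + f[n] * Sn
    xpow <- xpow * av
  }
  G <- G / (4 * pi * s1)
  G <- sweep(G, 2, colMeans(G))            # average reference
  structure(list(gain = G, head = head, montage = montage, mesh = mesh),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d electrodes x %d vertices (three-shell sphere)\n",
              nrow(x$gain), ncol(x$gain)))
  invisible(x)
}
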