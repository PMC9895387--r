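## Two-factor within-subject ANOVA with sphericity handling: classical
## sums-of-squares partition with subject-interaction error terms, Mauchly's
## test on orthonormal contrasts, Greenhouse-Geisser correction, partial eta
## squared, Bonferroni post hocs and paired t-tests.

#' Two-factor repeated-measures ANOVA
#'
#' Classical within-subject partition for a complete subjects x A x B
#' design: each effect (A, B, A x B) is tested against its interaction with
#' subjects. Sphericity is assessed per effect with Mauchly's test and the
#' Greenhouse-Geisser correction is reported; `p_gg` is used in place of the
#' uncorrected p whenever Mauchly's test rejects at `sphericity_alpha` (and
#' the effect has more than 1 numerator df).
#'
#' @param data Numeric array subjects x levels(A) x levels(B), complete.
#' @param factor_names Length-2 character, names of factors A and B.
#' @param sphericity_alpha Mauchly rejection level governing when the
#'   corrected p is adopted (default 0.05).
#' @return Object of class `rm_anova`: a data frame with one row per effect
#'   (`SS_effect`, `SS_error`, `df1`, `df2`, `F`, `epsilon_gg`,
#'   `df1_corrected`, `df2_corrected`, `p_uncorrected`, `p_gg`, `p`,
#'   `eta2p`, `mauchly_W`, `mauchly_p`).
#' @export
rm_anova_two_way <- function(data, factor_names = c("A", "B"),
                             sphericity_alpha = 0.05) {
  stop_if(length(dim(data)) != 3, "data must be subjects x A x B")
  n <- dim(data)[1]; a <- dim(data)[2]; b <- dim(data)[3]
  stop_if(n < 2, "need at least 2 subjects")
  stop_if(any(!is.finite(data)), "design must be complete and finite")
  gm <- mean(data)
  m_s <- apply(data, 1, mean); m_a <- apply(data, 2, mean)
  m_b <- apply(data, 3, mean)
  m_sa <- apply(data, c(1, 2), mean); m_sb <- apply(data, c(1, 3), mean)
  m_ab <- apply(data, c(2, 3), mean)
  SS_A <- n * b * sum((m_a - gm)^2)
  SS_B <- n * a * sum((m_b - gm)^2)
  SS_S <- a * b * sum((m_s - gm)^2)
  SS_AS <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + gm)^2)
  SS_BS <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + gm)^2)
  SS_AB <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  SS_tot <- sum((data - gm)^2)
  SS_ABS <- SS_tot - SS_A - SS_B - SS_S - SS_AS - SS_BS - SS_AB
  eff <- data.frame(
    effect = c(factor_names[1], factor_names[2],
               paste(factor_names, collapse = ":")),
    SS_effect = c(SS_A, SS_B, SS_AB),
    SS_error = c(SS_AS, SS_BS, SS_ABS),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1),
            (a - 1) * (b - 1) * (n - 1)),
    stringsAsFactors = FALSE)
  eff$F <- (eff$SS_effect / eff$df1) / (eff$SS_error / eff$df2)
  ## sphericity per effect on the subject-level contrast scores
  slices <- list(list(m_sa, TRUE), list(m_sb, TRUE),
                 list(interaction_scores(data), FALSE))
  sph <- lapply(slices, function(s)
    list(mauchly = mauchly_test(s[[1]], contrasts = s[[2]]),
         eps = greenhouse_geisser_epsilon(s[[1]], contrasts = s[[2]])))
  eff$epsilon_gg <- vapply(sph, function(s) s$eps, numeric(1))
  eff$df1_corrected <- eff$epsilon_gg * eff$df1
  eff$df2_corrected <- eff$epsilon_gg * eff$df2
  eff$p_uncorrected <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff$p_gg <- stats::pf(eff$F, eff$df1_corrected, eff$df2_corrected,
                        lower.tail = FALSE)
  eff$mauchly_W <- vapply(sph, function(s) s$mauchly["W"], numeric(1))
  eff$mauchly_p <- vapply(sph, function(s) s$mauchly["p"], numeric(1))
  use_gg <- eff$df1 > 1 & !is.na(eff$mauchly_p) &
    eff$mauchly_p < sphericity_alpha
  eff$p <- ifelse(use_gg, eff$p_gg, eff$p_uncorrected)
  eff$eta2p <- eff$SS_effect / (eff$SS_effect + eff$SS_error)
  structure(eff, class = c("rm_anova", "data.frame"))
}

## subject x (a-1)(b-1) interaction contrast scores via Kronecker contrasts
interaction_scores <- function(data) {
  n <- dim(data)[1]; a <- dim(data)[2]; b <- dim(data)[3]
  Ca <- orthonormal_contrasts(a); Cb <- orthonormal_contrasts(b)
  Y <- matrix(data, n, a * b)   # columns vary A fastest within B
  K <- kronecker(Cb, Ca)        # matching Kronecker contrast, (a*b) x (a-1)(b-1)
  Y %*% K
}

orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  qr.Q(qr(H))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (within-subject errors)\n")
  df <- as.data.frame(x)
  df$report <- sprintf("F(%.3f,%.3f) = %.3f, p = %.4f, eta2p = %.3f",
                       ifelse(df$p == df$p_gg & df$df1 > 1,
                              df$df1_corrected, df$df1),
                       ifelse(df$p == df$p_gg & df$df1 > 1,
                              df$df2_corrected, df$df2),
                       df$F, df$p, df$eta2p)
  print(df[, c("effect", "report")], row.names = FALSE)
  invisible(x)
}

#' Mauchly's test of sphericity
#'
#' `W` is the ratio of the determinant to the scaled trace power of the
#' covariance of orthonormal contrast scores; the p value uses the standard
#' chi-square approximation.
#'
#' @param Y Subjects x k matrix of within-subject measures (k >= 2), or
#'   subjects x (k-1) contrast scores if `contrasts = FALSE`.
#' @param contrasts If `TRUE` (default) Y holds raw level measures and
#'   orthonormal contrasts are applied first.
#' @return Named numeric `c(W = , p = , df = )`. For k = 2, `W = 1, p = 1`.
#' @export
mauchly_test <- function(Y, contrasts = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Z <- if (contrasts) Y %*% orthonormal_contrasts(ncol(Y)) else Y
  p <- ncol(Z)
  if (p < 2) return(c(W = 1, p = 1, df = 0))
  S <- stats::cov(Z)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-14 * max(ev))
    return(c(W = 0, p = 0, df = p * (p + 1) / 2 - 1))
  W <- prod(ev) / (mean(ev))^p
  df <- p * (p + 1) / 2 - 1
  ## chi-square approximation with the standard second-order correction
  nd <- n - 1
  rho <- 1 - (2 * p^2 + p + 2) / (6 * p * nd)
  w2 <- (p + 2) * (p - 1) * (p - 2) * (2 * p^3 + 6 * p^2 + 3 * p + 2) /
    (288 * p^2 * nd^2 * rho^2)
  z <- -nd * rho * log(W)
  pr1 <- stats::pchisq(z, df, lower.tail = FALSE)
  pr2 <- stats::pchisq(z, df + 4, lower.tail = FALSE)
  c(W = W, p = pr1 + w2 * (pr2 - pr1), df = df)
}

#' Greenhouse-Geisser epsilon
#'
#' Eigenvalue form on the covariance of orthonormal contrast scores:
#' `(sum lambda)^2 / ((k-1) sum lambda^2)`, bounded in `[1/(k-1), 1]`.
#'
#' @inheritParams mauchly_test
#' @return Epsilon.
#' @export
greenhouse_geisser_epsilon <- function(Y, contrasts = TRUE) {
  Y <- as.matrix(Y)
  Z <- if (contrasts) Y %*% orthonormal_contrasts(ncol(Y)) else Y
  if (ncol(Z) < 2) return(1)
  ev <- eigen(stats::cov(Z), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  sum(ev)^2 / (ncol(Z) * sum(ev^2))
}

#' Partial eta squared from an F statistic
#'
#' `eta2p = F df1 / (F df1 + df2)`, the standard effect size reported with
#' repeated-measures F tests.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (possibly
#'   non-integer after sphericity correction).
#' @return Fraction in `[0, 1]`.
#' @examples
#' eta_squared_partial(3.264, 3, 57)  # 0.147
#' @export
eta_squared_partial <- function(F, df1, df2) {
  stop_if(any(F < 0) || any(df1 <= 0) || any(df2 <= 0),
          "F must be >= 0 and dfs positive")
  F * df1 / (F * df1 + df2)
}

#' Bonferroni adjustment
#'
#' @param p_values Vector of raw p values in `[0, 1]`.
#' @param m Family size (default: the number of p values).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  stop_if(any(p_values < 0 | p_values > 1), "p values must lie in [0, 1]")
  stop_if(m < 1, "family size must be >= 1")
  pmin(1, m * p_values)
}

#' Paired t-test
#'
#' Classical two-sided paired t on the within-subject differences.
#'
#' @param x,y Paired observations of equal length (>= 2).
#' @return Named numeric `c(t = , df = , p = , mean_diff = )`.
#' @export
paired_t <- function(x, y) {
  stop_if(length(x) != length(y) || length(x) < 2,
          "x and y must be paired with length >= 2")
  d <- x - y
  stop_if(stats::sd(d) == 0 && mean(d) != 0,
          "zero-variance non-zero differences: t undefined")
  if (stats::sd(d) == 0) return(c(t = 0, df = length(d) - 1, p = 1,
                                  mean_diff = 0))
  tt <- stats::t.test(x, y, paired = TRUE)
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = unname(tt$estimate))
}
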