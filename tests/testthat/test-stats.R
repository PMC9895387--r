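test_that("RM-ANOVA partition matches the independent oracle exactly", {
  set.seed(100)
  for (rep in 1:6) {
    n <- sample(3:6, 1); a <- sample(2:3, 1); b <- sample(2:4, 1)
    X <- array(rnorm(n * a * b, sd = sample(1:3, 1)), c(n, a, b))
    res <- rm_anova_two_way(X)
    or <- aov_oracle(X)
    expect_equal(res$SS_effect, unname(c(or$A["SS"], or$B["SS"], or$AB["SS"])),
                 tolerance = 1e-9)
    expect_equal(res$SS_error,
                 unname(c(or$A_err["SS"], or$B_err["SS"], or$AB_err["SS"])),
                 tolerance = 1e-9)
    expect_equal(res$F, unname(c(or$A["F"], or$B["F"], or$AB["F"])),
                 tolerance = 1e-9)
    ## eta2p algebraic identity
    expect_equal(res$eta2p,
                 res$F * res$df1 / (res$F * res$df1 + res$df2),
                 tolerance = 1e-12)
  }
})

test_that("identical cells give zero F and constant data are rejected", {
  X <- array(rep(rnorm(5), 6), c(5, 2, 3))   # no condition effects
  res <- rm_anova_two_way(X)
  expect_equal(res$SS_effect, rep(0, 3), tolerance = 1e-12)
  expect_error(rm_anova_two_way(array(NA_real_, c(3, 2, 2))), "complete")
  expect_error(rm_anova_two_way(array(rnorm(8), c(1, 2, 4))), "2 subjects")
})

test_that("sphericity machinery agrees with independent implementations", {
  set.seed(101)
  n <- 12; k <- 4
  Y <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k), k) / 2
  mt <- stats::mauchly.test(lm(Y ~ 1), X = ~1)
  expect_equal(unname(mauchly_test(Y)["W"]), unname(mt$statistic),
               tolerance = 1e-9)
  ## the chi-square correction term differs in one coefficient from the
  ## base implementation; p values agree closely
  expect_equal(unname(mauchly_test(Y)["p"]), mt$p.value, tolerance = 0.01)
  skip_if_not_installed("car")
  idata <- data.frame(lev = factor(seq_len(k)))
  fit <- car::Anova(lm(Y ~ 1), idata = idata, idesign = ~lev, type = 3)
  s <- summary(fit, multivariate = FALSE)
  expect_equal(greenhouse_geisser_epsilon(Y), unname(s$pval.adjustments[
    "lev", "GG eps"]), tolerance = 1e-6)
})

test_that("Mauchly and GG behave correctly in the analytic edge cases", {
  set.seed(102)
  Y2 <- matrix(rnorm(20), 10, 2)
  expect_equal(unname(mauchly_test(Y2)[c("W", "p")]), c(1, 1))
  expect_equal(greenhouse_geisser_epsilon(Y2), 1)
  ## perfectly spherical contrast covariance
  Z <- matrix(rnorm(3000), 1000, 3)
  expect_gt(mauchly_test(Z)["W"], 0.98)
  expect_gt(greenhouse_geisser_epsilon(Z), 0.99)
  ## rank-1 structure drives epsilon to its lower bound and W to 0
  base <- rnorm(50)
  Yr <- outer(base, c(1, 2, 4, 8)) + 1e-8 * matrix(rnorm(200), 50)
  expect_lt(abs(greenhouse_geisser_epsilon(Yr) - 1 / 3), 0.01)
  expect_lt(mauchly_test(Yr)["W"], 1e-6)
  ## heterogeneous variances give W < 1
  Yh <- cbind(rnorm(40, sd = 0.5), rnorm(40, sd = 2), rnorm(40, sd = 5))
  expect_lt(mauchly_test(Yh)["W"], 1)
})

test_that("partial eta squared reproduces the published worked examples", {
  ## printed (F, df1, df2, eta2p) triples from the study this package models
  cases <- rbind(c(0.229, 1, 19, 0.012),
                 c(0.712, 3, 57, 0.036),
                 c(3.264, 3, 57, 0.147),
                 c(3.390, 3, 57, 0.151),
                 c(0.388, 1, 19, 0.020),
                 c(1.356, 3, 57, 0.067),
                 c(3.963, 3, 57, 0.173),
                 c(2.929, 3.287, 62.462, 0.134))
  expect_equal(round(eta_squared_partial(cases[, 1], cases[, 2], cases[, 3]), 3),
               cases[, 4])
  expect_equal(eta_squared_partial(0, 3, 57), 0)
})

test_that("Bonferroni and paired t follow their closed forms", {
  expect_equal(bonferroni_adjust(0.01, 6), 0.06)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), 1), c(0.2, 0.04))
  x <- c(1.1, 2.3, 0.7, 1.9, 2.5); y <- c(0.9, 2.0, 1.0, 1.2, 2.2)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  res <- paired_t(x, y)
  expect_equal(unname(res["t"]), t_hand, tolerance = 1e-12)
  expect_equal(unname(res["df"]), 4)
  expect_equal(unname(res["p"]), 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  same <- paired_t(x, x)
  expect_equal(unname(same[c("t", "p")]), c(0, 1))
  expect_error(paired_t(x + 1, x), "zero-variance")
})
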