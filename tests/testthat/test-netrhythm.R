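test_that("Green-function priors have the advertised support and shape", {
  ## sigma = 0: expm(0) = I, so each prior is the identity on its network
  p0 <- mesh_green_prior(fx$mesh, fx$atlas, sigma = 0)
  for (i in seq_along(p0$priors)) {
    idx <- fx$atlas$labels == i
    expect_equal(p0$priors[[i]][idx, idx], diag(sum(idx)))
    expect_true(all(p0$priors[[i]][!idx, ] == 0))
    expect_true(all(p0$priors[[i]][, !idx] == 0))
  }
  ## positive sigma: compare against a truncated-power-series oracle on a
  ## small mesh, check non-negativity and positive semidefiniteness
  small <- cortical_mesh(0)              # 12 vertices
  at <- synthetic_atlas(small, 2)
  sig <- 0.6
  W <- as.matrix(small$adjacency)
  W <- W / rowSums(W)
  G_oracle <- diag(12)
  term <- diag(12)
  for (k in 1:40) {
    term <- term %*% (sig * W) / k
    G_oracle <- G_oracle + term
  }
  G_pkg <- as.matrix(Matrix::expm(Matrix::Matrix(sig * W)))
  expect_equal(G_pkg, G_oracle, tolerance = 1e-10)
  expect_true(all(G_pkg >= 0))
  ps <- mesh_green_prior(small, at, sigma = sig)
  for (Vi in ps$priors) {
    expect_equal(Vi, t(Vi))
    ev <- eigen(Vi, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  expect_error(mesh_green_prior(fx$mesh, fx$atlas, sigma = -1), "sigma")
})

test_that("ReML with one identity prior equals the ridge closed form", {
  V <- ncol(fx$lead$gain); E <- nrow(fx$lead$gain)
  id_pri <- structure(list(priors = list(all = diag(V)), atlas = fx$atlas),
                      class = "covariance_priors")
  set.seed(13)
  X <- fx$lead$gain %*% matrix(rnorm(V * 400), V) +
    matrix(rnorm(E * 400, sd = 0.5), E)
  S <- tcrossprod(X) / 400
  fit <- reml_estimate(S, fx$lead, id_pri, n_samples = 400)
  h <- exp(fit$lambda)
  qs <- mean(diag(tcrossprod(fx$lead$gain)))
  ridge <- solve(crossprod(fx$lead$gain) + h[1] / (h[2] / qs) * diag(V)) %*%
    t(fx$lead$gain)
  expect_lt(norm(fit$operator - ridge, "F") / norm(ridge, "F"), 1e-6)
  expect_true(all(diff(fit$evidence) >= -1e-8))
})

test_that("ReML zero-covariance input yields vanishing posterior sources", {
  pri <- mesh_green_prior(fx$mesh, fx$atlas, 0.6)
  fit <- reml_estimate(matrix(0, 32, 32), fx$lead, pri, n_samples = 100)
  expect_lt(max(abs(fit$operator)), 1e-6)
  expect_true(all(is.finite(fit$lambda)))
})

test_that("band energies recover a planted network oscillation", {
  pri <- mesh_green_prior(fx$mesh, fx$atlas, 0.6)
  sp <- netgen_spec(active_network = "visual", band_hz = c(20, 30),
                    length_s = 16, snr = 10, seed = 17)
  rec <- simulate_network_eeg(sp, fx$lead, fx$atlas)
  ep <- epoch_fixed_length(rec, 2)
  en <- band_energies(ep, fx$lead, pri)
  expect_equal(dim(en), c(8, 7))
  expect_true(all(en >= 0))
  expect_equal(unname(which.max(en[, "beta2"])), 1L)
  ## beta2 dominates the visual row as well
  expect_equal(unname(which.max(en["visual", ])),
               which(band_definition()$name == "beta2"))
  ## scaling all sensor data by c scales every energy by c^2
  ep3 <- ep; ep3$epochs <- lapply(ep$epochs, function(e) 3 * e)
  en3 <- band_energies(ep3, fx$lead, pri)
  expect_equal(as.vector(en3), as.vector(9 * en), tolerance = 1e-6)
  ## zero input gives zero energies
  ep0 <- ep; ep0$epochs <- lapply(ep$epochs, function(e) e * 0)
  expect_true(all(band_energies(ep0, fx$lead, pri) == 0))
})

test_that("each planted network attains the top energy in its band", {
  pri <- mesh_green_prior(fx$mesh, fx$atlas, 0.6)
  top <- vapply(1:8, function(net) {
    sp <- netgen_spec(active_network = net, band_hz = c(8, 13),
                      length_s = 12, snr = 10, seed = 600 + net)
    rec <- simulate_network_eeg(sp, fx$lead, fx$atlas)
    ep <- epoch_fixed_length(rec, 2)
    en <- band_energies(ep, fx$lead, pri)
    which.max(en[, "alpha1"] + en[, "alpha2"])
  }, integer(1))
  expect_equal(top, 1:8)
})
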