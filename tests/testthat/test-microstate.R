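test_that("GFP matches its defining formula", {
  expect_equal(gfp(c(5, 5, 5)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  set.seed(1)
  v <- rnorm(32)
  expect_equal(gfp(v), gfp_oracle(v))
  X <- matrix(rnorm(32 * 10), 32)
  expect_equal(gfp(X), apply(X, 2, gfp_oracle))
})

test_that("absolute spatial correlation is a polarity-blind Pearson r", {
  set.seed(2)
  a <- rnorm(32); b <- rnorm(32)
  expect_equal(spatial_correlation_abs(a, b), abs(cor(a, b)))
  expect_equal(spatial_correlation_abs(a, a), 1)
  expect_equal(spatial_correlation_abs(a, -a), 1)
  ## orthogonal zero-mean maps
  u <- c(1, -1, 0, 0); v <- c(0, 0, 1, -1)
  expect_equal(spatial_correlation_abs(u, v), 0)
  expect_error(spatial_correlation_abs(rep(1, 4), v), "zero-variance")
})

test_that("GFP peak extraction keeps strict local maxima only", {
  ## craft a 2-channel recording with GFP series 1,3,2,4,1
  g <- c(1, 3, 2, 4, 1)
  rec <- eeg_recording(rbind(g, -g), 250, fx$montage[1:2, ])
  ts <- extract_gfp_peaks(rec)
  expect_equal(ts$source_times, c(2, 4))
  expect_equal(rowMeans(ts$maps), c(0, 0))
  mono <- eeg_recording(rbind(1:5, -(1:5)), 250, fx$montage[1:2, ])
  ts2 <- extract_gfp_peaks(mono)
  expect_true(attr(ts2, "empty"))
  expect_equal(nrow(ts2$maps), 0)
})

test_that("polarity-invariant k-means recovers exact mixtures", {
  tpl <- make_template_maps(2, fx$montage, seed = 5)
  set.seed(6)
  signs <- sample(c(-1, 1), 60, replace = TRUE)
  maps <- tpl[rep(1:2, 30), ] * signs
  fit <- microstate_fit(maps, 2, n_restarts = 5, seed = 1)
  S <- restate:::map_corr_matrix(coef(fit), tpl)
  expect_equal(sort(apply(S, 2, max)), c(1, 1), tolerance = 1e-9)
  expect_equal(fit$gev_total, 1, tolerance = 1e-9)
  ## k = n_maps gives a perfect fit
  small <- make_template_maps(3, fx$montage, seed = 8)
  expect_equal(microstate_fit(small, 3, n_restarts = 3, seed = 1)$gev_total,
               1, tolerance = 1e-9)
  expect_error(microstate_fit(small, 5), "at least k maps")
})

test_that("k-means attains the exhaustive-partition optimum for k = 2", {
  set.seed(7)
  for (rep in 1:3) {
    maps <- matrix(rnorm(8 * 16), 8)
    w <- runif(8, 0.5, 2)
    tset <- structure(list(maps = maps, gfp_at_peak = w,
                           source_times = 1:8), class = "topography_set")
    fit <- microstate_fit(tset, 2, n_restarts = 40, seed = rep)
    ## the exhaustive global optimum is never below the k-means solution
    expect_gte(best_gev_k2_oracle(maps, w), fit$gev_total - 1e-9)
  }
})

test_that("flipping sample polarity leaves the whole analysis unchanged", {
  spec <- msgen_spec(length_s = 10, seed = 21)
  rec <- simulate_microstate_eeg(spec, fx$montage)
  rec <- ms_prep(rec)
  flip <- rec
  set.seed(9)
  idx <- sample(ncol(flip$data), ncol(flip$data) / 2)
  flip$data[, idx] <- -flip$data[, idx]
  f1 <- microstate_fit(extract_gfp_peaks(rec), 4, n_restarts = 10, seed = 2)
  f2 <- microstate_fit(extract_gfp_peaks(flip), 4, n_restarts = 10, seed = 2)
  expect_equal(abs(f1$prototypes), abs(f2$prototypes), tolerance = 1e-6)
  expect_equal(f1$gev_total, f2$gev_total, tolerance = 1e-9)
  s1 <- backfit(rec, f1); s2 <- backfit(flip, f1)
  expect_identical(s1$labels, s2$labels)
  expect_equal(s1$corr_series, s2$corr_series, tolerance = 1e-9)
})

test_that("GEV is non-decreasing in k under nested warm starts", {
  spec <- msgen_spec(length_s = 10, seed = 22)
  ts <- extract_gfp_peaks(ms_prep(simulate_microstate_eeg(spec, fx$montage)))
  Xn <- restate:::normalize_maps(ts$maps)
  prev <- NULL
  gevs <- c()
  for (k in 2:6) {
    init <- if (!is.null(prev))
      rbind(prev$prototypes, Xn[seq_len(k - prev$k), , drop = FALSE])
    fit <- microstate_fit(ts, k, n_restarts = 5, seed = k, init = init)
    gevs <- c(gevs, fit$gev_total)
    prev <- fit
  }
  expect_true(all(diff(gevs) >= -1e-12))
  expect_true(all(gevs >= 0 & gevs <= 1))
})

test_that("group maps pool subjects and order classes by the reference", {
  tpl <- make_template_maps(4, fx$montage, seed = 31)
  models <- lapply(1:3, function(i) {
    spec <- msgen_spec(templates = tpl, length_s = 10, seed = 40 + i)
    microstate_fit(extract_gfp_peaks(
      ms_prep(simulate_microstate_eeg(spec, fx$montage))),
      4, n_restarts = 10, seed = i)
  })
  gm <- group_maps_two_stage(models, 4, reference = tpl, n_restarts = 10,
                             seed = 1)
  S <- restate:::map_corr_matrix(gm$prototypes, tpl)
  expect_true(all(diag(S) >= 0.95))
  ## degenerate pooling: identical subject models reproduce themselves
  same <- list(models[[1]], models[[1]])
  gm2 <- group_maps_two_stage(same, 4, reference = tpl, n_restarts = 5,
                              seed = 1)
  S2 <- restate:::map_corr_matrix(gm2$prototypes,
                                  restate:::order_classes(models[[1]], tpl)$prototypes)
  expect_equal(diag(S2), rep(1, 4), tolerance = 1e-9)
  expect_error(group_maps_two_stage(models, 20), "pooled")
})

test_that("backfit labels peaks by correlation and fills by nearest peak", {
  ## four-channel recording with known GFP peaks at samples 10 and 20:
  ## peak 10 carries the map of class A, peak 20 the map of class B
  n <- 25
  model <- structure(list(
    k = 2,
    prototypes = restate:::normalize_maps(rbind(c(1, -1, 0, 0),
                                                c(0, 0, 1, -1))),
    class_names = c("A", "B")), class = "microstate_model")
  X4 <- matrix(0, 4, n)
  X4[1:2, ] <- 0.05 * c(1, -1)
  X4[, 10] <- c(1, -1, 0, 0); X4[, 20] <- c(0, 0, 1, -1)
  rec <- eeg_recording(X4, 250, fx$montage[1:4, ])
  seg <- backfit(rec, model)
  expect_equal(seg$peaks, c(10, 20))
  ## midpoint rule with ties to the earlier peak: boundary after sample 15
  expect_true(all(seg$labels[1:15] == 1))
  expect_true(all(seg$labels[16:25] == 2))
})

test_that("temporal parameters follow their closed forms", {
  seg <- structure(list(labels = c(1, 1, 2, 2), corr_series = rep(1, 4),
                        fs_hz = 2, peaks = 1:4, k = 2),
                   class = "segmentation")
  rec <- eeg_recording(rbind(c(1, 1, 1, 1), c(-1, -1, 1, 1),
                             c(0, 0, -2, -2)), 2, fx$montage[1:3, ])
  st <- microstate_stats(seg, rec)
  expect_equal(st$duration_ms, c(1000, 1000))
  expect_equal(st$occurrence_per_s, c(0.5, 0.5))
  expect_equal(st$coverage, c(0.5, 0.5))
  ## GEV sums to 1 for a perfect fit (corr = 1 everywhere)
  expect_equal(sum(st$gev), 1)
  ## a never-observed state reports NA duration, zero occurrence/coverage
  seg3 <- structure(list(labels = rep(1, 10), corr_series = rep(1, 10),
                         fs_hz = 10, peaks = 1:10, k = 2),
                    class = "segmentation")
  rec3 <- eeg_recording(matrix(rnorm(30), 3), 10, fx$montage[1:3, ])
  st3 <- microstate_stats(seg3, rec3)
  expect_true(is.na(st3$duration_ms[2]))
  expect_equal(st3$occurrence_per_s[2], 0)
  expect_equal(st3$coverage, c(1, 0))
})

test_that("transition fractions count run boundaries and sum to one", {
  seg <- structure(list(labels = c(1, 1, 2, 3, 3), k = 3, fs_hz = 10),
                   class = "segmentation")
  tm <- transition_probabilities(seg)
  expect_equal(tm$probs["A", "B"], 0.5)
  expect_equal(tm$probs["B", "C"], 0.5)
  expect_equal(sum(tm$probs), 1)
  expect_equal(sum(diag(tm$counts)), 0)
  one <- structure(list(labels = rep(2, 5), k = 3), class = "segmentation")
  tm2 <- transition_probabilities(one)
  expect_true(attr(tm2, "no_transitions"))
  expect_equal(sum(tm2$counts), 0)
})

test_that("estimated switch fractions converge to the generating chain", {
  P <- matrix(c(0, .6, .2, .2,
                .3, 0, .4, .3,
                .2, .3, 0, .5,
                .4, .4, .2, 0), 4, 4, byrow = TRUE)
  spec <- msgen_spec(n_states = 4, transition_bias = P, fs_hz = 250,
                     length_s = 600, seed = 77)
  lab <- simulate_state_sequence(spec)
  seg <- structure(list(labels = as.vector(lab), k = 4, fs_hz = 250),
                   class = "segmentation")
  tm <- transition_probabilities(seg)
  ex <- expected_state_stats(spec)$transition_probs
  expect_lt(max(abs(tm$probs - ex)), 0.02)
})
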