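test_that("template maps are zero-mean, unit-norm and well separated", {
  tpl <- make_template_maps(4, fx$montage, seed = 7)
  expect_equal(rowMeans(tpl), rep(0, 4), tolerance = 1e-12)
  expect_equal(rowSums(tpl^2), rep(1, 4), tolerance = 1e-12)
  S <- restate:::map_corr_matrix(tpl, tpl)
  expect_lt(max(S[upper.tri(S)]), 0.9)
  ## determinism and the single-map degenerate case
  expect_identical(tpl, make_template_maps(4, fx$montage, seed = 7))
  one <- make_template_maps(1, fx$montage, seed = 1)
  expect_equal(sum(one^2), 1, tolerance = 1e-12)
  ## an infeasible separation constraint is reported, not looped forever
  expect_error(make_template_maps(25, fx$montage[1:3, ], seed = 1,
                                  max_abs_corr = 0.05, max_tries = 10),
               "could not draw")
})

test_that("state sequences respect the embedded chain and dwell means", {
  ## forced cycle A -> B -> C -> A: only those transitions appear
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1
  spec <- msgen_spec(n_states = 3, transition_bias = P, fs_hz = 250,
                    length_s = 60, seed = 4)
  lab <- simulate_state_sequence(spec)
  runs <- rle(as.vector(lab))$values
  steps <- cbind(runs[-length(runs)], runs[-1])
  expect_true(all(steps[, 2] == steps[, 1] %% 3 + 1))

  ## empirical dwell means converge to the specification (law of large numbers)
  spec2 <- msgen_spec(n_states = 2, mean_duration_ms = 100, fs_hz = 250,
                      length_s = 600, seed = 5)
  lab2 <- simulate_state_sequence(spec2)
  r <- rle(as.vector(lab2))
  for (s in 1:2)
    expect_lt(abs(mean(r$lengths[r$values == s]) * 4 - 100) / 100, 0.05)

  ## single state -> constant sequence; bad chain rejected
  expect_true(all(simulate_state_sequence(msgen_spec(1, length_s = 1)) == 1))
  bad <- matrix(c(0, 0.5, 1, 0), 2, 2, byrow = TRUE)
  expect_error(msgen_spec(n_states = 2, transition_bias = bad), "sum to 1")
})

test_that("rendering is exact in the noiseless limit and polarity-blind", {
  tpl <- make_template_maps(2, fx$montage, seed = 2)
  spec <- msgen_spec(n_states = 2, templates = tpl, noise_sd = 0,
                     fs_hz = 250, length_s = 4, render_band = NULL, seed = 9)
  lab <- simulate_state_sequence(spec)
  rec <- render_eeg(lab, spec, fx$montage)
  ## every sample is proportional to its template (rank-1 per sample),
  ## so |spatial correlation| to the template is 1 whatever the sign
  for (t in seq(1, 1000, by = 83)) {
    a <- rec$data[, t]
    if (sqrt(sum(a^2)) < 1e-9) next
    expect_equal(spatial_correlation_abs(a, tpl[lab[t], ]), 1,
                 tolerance = 1e-9)
  }
  ## zero-mean templates render to (near-)zero channel means
  expect_lt(max(abs(colMeans(rec$data))), 1e-10)
  ## determinism of the full generator
  r1 <- simulate_microstate_eeg(msgen_spec(length_s = 2, seed = 3), fx$montage)
  r2 <- simulate_microstate_eeg(msgen_spec(length_s = 2, seed = 3), fx$montage)
  expect_identical(r1$data, r2$data)
})

test_that("analytic expected statistics match long-run empirical rates", {
  P <- matrix(c(0, .5, .3, .2,
                .2, 0, .5, .3,
                .3, .2, 0, .5,
                .5, .3, .2, 0), 4, 4, byrow = TRUE)
  spec <- msgen_spec(n_states = 4, mean_duration_ms = c(80, 100, 120, 140),
                     transition_bias = P, fs_hz = 250, length_s = 600,
                     seed = 13)
  ex <- expected_state_stats(spec)
  lab <- simulate_state_sequence(spec)
  r <- rle(as.vector(lab))
  n <- length(lab)
  for (s in 1:4) {
    expect_lt(abs(mean(r$lengths[r$values == s]) * 4 /
                    ex$duration_ms[s] - 1), 0.05)
    expect_lt(abs(sum(r$lengths[r$values == s]) / n /
                    ex$coverage[s] - 1), 0.05)
    expect_lt(abs(sum(r$values == s) / 600 /
                    ex$occurrence_per_s[s] - 1), 0.05)
  }
  ## switch fractions: compare empirical pair frequencies to the ledger
  steps <- table(factor(r$values[-length(r$values)], 1:4),
                 factor(r$values[-1], 1:4)) / (length(r$values) - 1)
  expect_lt(max(abs(steps - ex$transition_probs)), 0.02)
})

test_that("network EEG lies in the active network's column space", {
  sp <- netgen_spec(active_network = "visual", band_hz = c(20, 30),
                    noise_sd = 0, fs_hz = 250, length_s = 4, seed = 3)
  rec <- simulate_network_eeg(sp, fx$lead, fx$atlas)
  idx <- fx$atlas$labels == 1
  G1 <- fx$lead$gain[, idx]
  resid <- rec$data - G1 %*% qr.solve(G1, rec$data)
  expect_lt(max(abs(resid)), 1e-8 * max(abs(rec$data)))
  ## quadratic energy scaling and the zero-source case
  gt1 <- attr(rec, "ground_truth")$true_energy
  sp2 <- sp; sp2$source_amp <- 2
  gt2 <- attr(simulate_network_eeg(sp2, fx$lead, fx$atlas),
              "ground_truth")$true_energy
  expect_equal(unname(gt2[1] / gt1[1]), 4, tolerance = 1e-12)
  expect_equal(unname(gt1[-1]), rep(0, 7))
  sp0 <- netgen_spec(source_amp = 0, noise_sd = 1, length_s = 2, seed = 1)
  gt0 <- attr(simulate_network_eeg(sp0, fx$lead, fx$atlas),
              "ground_truth")$true_energy
  expect_true(all(gt0 == 0))
})

test_that("cohort effects plant the requested parameter shifts", {
  eff <- list(state_C_duration = 1.5, state_D_coverage = 0.8,
              AC_transition = 1.5, BD_transition = 0.7, visual_beta2 = 1.4)
  spec <- cohort_spec(n_subjects = 3, effects = eff,
                      base_ms = msgen_spec(length_s = 2),
                      base_net = netgen_spec(length_s = 2), seed = 1)
  cohort <- simulate_cohort(spec, fx$montage, lead = fx$lead,
                            atlas = fx$atlas)
  led <- cohort$ledger
  expect_equal(led$expected_post$duration_ms[3] /
                 led$expected_pre$duration_ms[3], 1.5)
  ## the D dwell rescaling hits the planted coverage ratio exactly
  expect_equal(led$expected_post$coverage[4] / led$expected_pre$coverage[4],
               0.8, tolerance = 1e-10)
  expect_equal(unname(led$amp_post["visual", "beta2"]), 1.4)
  expect_equal(led$amp_post[-1, ], led$amp_pre[-1, ])
  ## A<->C switch fractions rise, B<->D fall
  tp0 <- led$expected_pre$transition_probs
  tp1 <- led$expected_post$transition_probs
  expect_gt(tp1[1, 3] / tp0[1, 3], 1)
  expect_gt(tp1[3, 1] / tp0[3, 1], 1)
  expect_lt(tp1[2, 4] / tp0[2, 4], 1)
  expect_lt(tp1[4, 2] / tp0[4, 2], 1)
  ## a null cohort leaves the generator parameters untouched
  null_post <- restate:::apply_ms_effects(spec$base_ms,
    stats::setNames(as.list(rep(1, 5)), names(eff)))
  expect_equal(null_post, spec$base_ms)
  expect_error(cohort_spec(n_subjects = 1), "2 subjects")
  expect_error(cohort_spec(effects = list(bogus = 2)), "unknown effect")
})
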