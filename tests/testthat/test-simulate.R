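test_that("simulators are byte-identical under a fixed seed", {
  truth <- simulate_cohort_truth(30, seed = 5)
  truth2 <- simulate_cohort_truth(30, seed = 5)
  expect_identical(truth, truth2)

  des <- sim_design(seed = 6)
  s1 <- simulate_timecourse_counts(truth, des)
  s2 <- simulate_timecourse_counts(truth, des)
  expect_identical(s1, s2)

  a1 <- simulate_annotations(20, 10, 1e6, seed = 7)
  a2 <- simulate_annotations(20, 10, 1e6, seed = 7)
  expect_identical(a1, a2)

  p1 <- simulate_replicate_peaks(truth, 3, 5, 0.2, seed = 8)
  p2 <- simulate_replicate_peaks(truth, 3, 5, 0.2, seed = 8)
  expect_identical(p1, p2)
})

test_that("zero-noise high-count simulation reproduces the decay curve", {
  # constant-ratio law of large numbers
  truth <- sim_feature_truth("f1", "chrXsim", 0, 500, true_y0 = 0,
                             true_yf = 0.5, true_k = 0, mean_total = 1e6,
                             dispersion = 0, allelic_fraction = 1, rho = 0)
  sim <- simulate_timecourse_counts(truth, sim_design(seed = 9))
  r <- allelic_ratio(sim$counts$xi, sim$counts$xa)
  expect_true(all(abs(r - 0.5) < 0.001))

  # expected ratio at day 1 for y0 = 0.5, yf = 0, k = ln 2 is 0.25
  truth2 <- sim_feature_truth("f2", "chrXsim", 0, 500, true_y0 = 0.5,
                              true_yf = 0, true_k = log(2),
                              mean_total = 1e6, dispersion = 0,
                              allelic_fraction = 1, rho = 0)
  sim2 <- simulate_timecourse_counts(truth2, sim_design(seed = 10))
  d1 <- sim2$design$day == 1
  r1 <- allelic_ratio(sim2$counts$xi[, d1], sim2$counts$xa[, d1])
  expect_true(all(abs(r1 - 0.25) < 0.005))

  # full curve match to three decimals at every timepoint
  truth3 <- sim_feature_truth("f3", "chrXsim", 0, 500, true_y0 = 0.4,
                              true_yf = 0.1, true_k = 0.3,
                              mean_total = 1e6, dispersion = 0,
                              allelic_fraction = 1, rho = 0)
  sim3 <- simulate_timecourse_counts(truth3, sim_design(seed = 11))
  r3 <- as.numeric(allelic_ratio(sim3$counts$xi, sim3$counts$xa))
  expect_true(all(abs(r3 - (0.1 + 0.4 * exp(-0.3 * sim3$design$day))) <
                    0.001))
})

test_that("gainer features show increasing mean allelic ratio over time", {
  truth <- sim_feature_truth("g1", "chrXsim", 0, 500, true_y0 = -0.3,
                             true_yf = 0.8, true_k = 0.5, mean_total = 5e4,
                             dispersion = 0, allelic_fraction = 1, rho = 0,
                             labels = "gainer")
  sim <- simulate_timecourse_counts(truth, sim_design(seed = 12))
  rt <- ratio_timecourse(sim$counts, sim$design)
  expect_true(all(diff(rt$ratio[1, ]) > 0))
})

test_that("simulated totals match negative-binomial moments", {
  truth <- sim_feature_truth(sprintf("f%d", 1:2500), "chrXsim",
                             (1:2500) * 1e3, (1:2500) * 1e3 + 500,
                             true_y0 = 0.4, true_yf = 0.1, true_k = 0.3,
                             mean_total = 300, dispersion = 0.1)
  des <- sim_design(timepoints = c(0, 1, 3), replicates_per_timepoint = 2,
                    seed = 13)
  sim <- simulate_timecourse_counts(truth, des)
  tot <- as.numeric(sim$counts$total)  # 15000 draws
  expect_equal(mean(tot), 300, tolerance = 0.02)
  expect_equal(var(tot), 300 + 0.1 * 300^2, tolerance = 0.05)
})

test_that("invalid truth parameters are rejected naming the feature", {
  expect_error(sim_feature_truth("bad1", "c", 0, 100, true_y0 = 0.9,
                                 true_yf = 0.3, true_k = 1),
               "bad1")
  expect_error(sim_feature_truth("x", "c", 100, 100, 0.4, 0.1, 1), "start")
  expect_error(sim_design(timepoints = c(1, 3)), "day 0")
})

test_that("annotation simulation places the configured TSS overlaps", {
  ann <- simulate_annotations(100, 40, 1e6, seed = 7,
                              tss_overlap_frac = 0.5)
  expect_equal(nrow(ann$tss), 100)
  expect_equal(nrow(ann$tf_peaks), 40)
  # brute-force overlap count: exactly half the peaks contain a TSS point
  n_over <- sum(vapply(seq_len(nrow(ann$tf_peaks)), function(i) {
    any(ann$tss$tss >= ann$tf_peaks$start[i] &
          ann$tss$tss < ann$tf_peaks$end[i])
  }, logical(1)))
  expect_equal(n_over, 20)

  one <- simulate_annotations(1, 0, 1e6, seed = 1)
  expect_equal(nrow(one$tss), 1)
  expect_equal(nrow(one$tf_peaks), 0)
  expect_error(simulate_annotations(0, 5, 1e6), "sizes")
})

test_that("replicate peak simulation respects dropout and jitter contracts", {
  truth <- simulate_cohort_truth(50, seed = 14)
  clean <- simulate_replicate_peaks(truth, 2, jitter_sd = 0,
                                    dropout_rate = 0, seed = 15)
  for (rs in clean) {
    expect_equal(rs$start, truth$start)
    expect_equal(rs$end, truth$end)
  }

  noisy <- simulate_replicate_peaks(simulate_cohort_truth(1000, seed = 16),
                                    2, 10, dropout_rate = 0.5, seed = 17)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  for (rs in noisy) {
    expect_gte(nrow(rs), bounds[1])
    expect_lte(nrow(rs), bounds[2])
  }

  expect_error(simulate_replicate_peaks(truth, 1), "n_replicates")
  expect_error(simulate_replicate_peaks(truth, 2, jitter_sd = -1), "jitter")
})

test_that("degron simulation scales Xi means only, as programmed", {
  truth <- simulate_cohort_truth(300, seed = 18, mean_total = 2000,
                                 dispersion = 0.01)
  des <- sim_design(timepoints = c(0, 2, 6), seed = 19)

  # null effect: identical distributions in expectation
  null <- simulate_degron_counts(truth, des, target_effect = 1,
                                 offtarget_effect = 1)
  fc0 <- allelic_log2fc(libsize_normalize(null$treated),
                        libsize_normalize(null$control), "Xi")
  expect_lt(abs(median(fc0, na.rm = TRUE)), 0.05)

  # halved Xi at targets: median log2 fold changes hit -1 (Xi) and 0 (Xa)
  eff <- simulate_degron_counts(truth, des, target_effect = 0.5,
                                offtarget_effect = 1)
  trn <- libsize_normalize(eff$treated); ctn <- libsize_normalize(eff$control)
  targets <- truth$feature_id[grepl("yy1_target", truth$labels)]
  fc_xi <- allelic_log2fc(trn, ctn, "Xi")
  fc_xa <- allelic_log2fc(trn, ctn, "Xa")
  expect_equal(median(fc_xi[targets], na.rm = TRUE), -1, tolerance = 0.05)
  expect_equal(median(fc_xa, na.rm = TRUE), 0, tolerance = 0.05)

  expect_error(simulate_degron_counts(truth, des, target_effect = 0),
               "multipliers")
})
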