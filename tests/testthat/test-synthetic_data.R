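test_that("simulation configs are validated", {
  expect_error(simulation_config(p_no_loss = 0.5, p_segmental = 0.5,
                                 p_complete = 0.5), "must equal 1")
  expect_error(simulation_config(baseline_hazard = 0), "positive")
  expect_error(simulation_config(p_artifact = 1.5), "\\[0, 1\\]")
  bad_mix <- default_mc_mixture()
  bad_mix[1, ] <- bad_mix[1, ] * 2
  expect_error(simulation_config(mc_mixture = bad_mix), "mc_mixture")
  expect_error(simulation_config(grade_probs = list(
    no_loss = c(1, 0), loss = c(1, 0, 0))), "grade_probs")
})

test_that("a degenerate no-loss mixture yields all-zero profiles", {
  cfg <- simulation_config(n_subjects = 25, n_cohorts = 1,
                           p_no_loss = 1, p_segmental = 0, p_complete = 0,
                           p_artifact = 0, p_gain = 0, noise_sd = 0,
                           seed = 4)
  co <- simulate_cohort(cfg)
  arms <- load_cytobands(cfg$cytoband)
  prof <- arm_profiles(co$segments, arms, "chr1p")
  expect_true(all(prof$loss_percent == 0))
  expect_true(all(prof$extent_category == "none"))
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- simulation_config(n_subjects = 40, n_cohorts = 2, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$segments, b$segments)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(simulation_config(n_subjects = 40, n_cohorts = 2,
                                         seed = 124))
  expect_false(identical(a$segments, c$segments))
})

test_that("every clinical sample has segments and a truth entry", {
  co <- simulate_cohort(simulation_config(n_subjects = 30, n_cohorts = 2,
                                          seed = 8))
  expect_setequal(unique(co$segments$sample_id), co$clinical$sample_id)
  expect_identical(co$truth$sample_id, co$clinical$sample_id)
  expect_silent(validate_segments(co$segments))
  expect_silent(validate_clinical(co$clinical))
})

test_that("empirical marginals converge to configured rates", {
  cfg <- simulation_config(n_subjects = 2000, n_cohorts = 1, seed = 202)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  n <- nrow(tr)
  expect_equal(mean(tr$stratum == "none"), cfg$p_no_loss, tolerance = 0.03)
  expect_equal(mean(tr$stratum == "complete"), cfg$p_complete,
               tolerance = 0.03)
  # artifacts appear in truly intact samples at the configured rate
  # (within one percentage point)
  expect_lt(abs(sum(tr$artifact_1p) / sum(tr$stratum == "none") -
                  cfg$p_artifact), 0.01)
  # 22q co-occurrence
  expect_equal(mean(tr$loss_22q[tr$loss_1p]), cfg$p_22q_given_loss,
               tolerance = 0.04)
  expect_equal(mean(tr$loss_22q[!tr$loss_1p]), cfg$p_22q_given_none,
               tolerance = 0.04)
  # censoring fraction for the no-loss stratum: c / (c + lambda0)
  cl <- co$clinical[!tr$loss_1p, ]
  expect_equal(mean(cl$event == 0),
               cfg$censoring_rate /
                 (cfg$censoring_rate + cfg$baseline_hazard),
               tolerance = 0.04)
})

test_that("measured 1-5% losses track the artifact rate", {
  cfg <- simulation_config(n_subjects = 2000, n_cohorts = 1, seed = 303)
  co <- simulate_cohort(cfg)
  arms <- load_cytobands(cfg$cytoband)
  prof <- arm_profiles(co$segments, arms, "chr1p")
  frac_1_5 <- mean(prof$loss_percent >= 1 & prof$loss_percent <= 5)
  # artifacts arise only in the no-loss stratum; one-percentage-point band
  expect_lt(abs(frac_1_5 - cfg$p_artifact * cfg$p_no_loss), 0.01)
  # and the loss distribution is bimodal: 0% and 96-100% dominate
  b <- bin_distribution(prof, 5)
  mass_ends <- (b$count[b$bin == "0"] + b$count[b$bin == "96-100"]) /
    sum(b$count)
  expect_gt(mass_ends, 0.8)
})

test_that("methylation classes follow the extent-interpolated mixture", {
  cfg <- simulation_config(n_subjects = 3000, n_cohorts = 1, seed = 404)
  co <- simulate_cohort(cfg)
  ben <- c("Ben-1", "Ben-2", "Ben-3")
  none <- co$truth$stratum == "none"
  complete <- co$truth$stratum == "complete"
  # 94% benign at 0% loss, 72% intermediate/malignant at complete loss
  expect_equal(mean(co$clinical$mc_class[none] %in% ben), 0.94,
               tolerance = 0.03)
  expect_equal(mean(!(co$clinical$mc_class[complete] %in% ben)), 0.72,
               tolerance = 0.04)
})

test_that("partial losses are telomere-anchored unless interstitial", {
  cfg <- simulation_config(n_subjects = 400, n_cohorts = 1,
                           p_no_loss = 0, p_segmental = 1, p_complete = 0,
                           p_artifact = 0, p_gain = 0, seed = 15)
  co <- simulate_cohort(cfg)
  arms <- load_cytobands(cfg$cytoband)
  arm1p <- get_arm(arms, "chr1p")
  loss_seg <- co$segments[co$segments$chrom == "chr1" &
                            co$segments$start < arm1p$end &
                            co$segments$log2_ratio < -0.15, ]
  # every sample's loss territory starts at the arm (= telomere) start
  first_loss <- tapply(loss_seg$start, loss_seg$sample_id, min)
  expect_true(all(first_loss == arm1p$start))

  # per-base loss coverage decreases monotonically from telomere
  # to centromere for telomere-anchored extents
  prof <- arm_profiles(co$segments, arms, "chr1p")
  mids <- seq(0.05, 0.95, by = 0.1)
  cover <- vapply(mids, function(m) {
    pos <- arm1p$start + m * arm1p$length
    sum(loss_seg$start <= pos & loss_seg$end > pos)
  }, 0)
  expect_true(all(diff(cover) <= 0))
})

test_that("truth recovery is perfect without noise and null without signal", {
  cfg <- simulation_config(n_subjects = 300, n_cohorts = 1, noise_sd = 0,
                           seed = 5150)
  co <- simulate_cohort(cfg)
  arms <- load_cytobands(cfg$cytoband)
  prof <- arm_profiles(co$segments, arms, "chr1p")
  rep5 <- truth_recovery_report(co, prof, cutoff_percent = 5)
  expect_equal(rep5$accuracy, 1)
  expect_equal(sum(diag(rep5$confusion)), nrow(co$clinical))

  # hazard ratio 1: the loss call carries no prognostic information
  cfg0 <- simulation_config(n_subjects = 2000, n_cohorts = 1, hr_loss = 1,
                            hr_co_loss = 1, noise_sd = 0, seed = 606)
  co0 <- simulate_cohort(cfg0)
  prof0 <- arm_profiles(co0$segments, load_cytobands(cfg0$cytoband),
                        "chr1p")
  rep0 <- truth_recovery_report(co0, prof0, 5)
  expect_equal(rep0$c_index$c_index, 0.5, tolerance = 0.02)
})
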