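# small deterministic profile/clinical pair builder
toy_profiles <- function(lp, ids = sprintf("s%d", seq_along(lp)),
                         arm_label = "chr1p") {
  data.frame(sample_id = ids, chrom = "chr1", arm = "p",
             arm_label = arm_label,
             loss_fraction = lp / 100, gain_fraction = 0,
             neutral_fraction = 1 - lp / 100,
             loss_percent = as.integer(lp),
             extent_category = classify_extent(lp),
             stringsAsFactors = FALSE)
}

toy_clinical <- function(time, event, ids = sprintf("s%d", seq_along(time)),
                         cohort = "discovery", who_grade = 1) {
  data.frame(sample_id = ids, time = time, event = event,
             who_grade = who_grade, mc_class = NA_character_,
             cohort = cohort, stringsAsFactors = FALSE)
}

test_that("perfect separation reaches the binary-score concordance ceiling", {
  # loss cases recur first, all events.  With a dichotomous score the 9
  # cross-group pairs are all concordant and the 6 comparable within-group
  # pairs are score-tied (1/2 credit each), so the maximum attainable
  # c-index is (9 + 0.5 * 6) / 15 = 0.8 at every cut-off.
  prof <- toy_profiles(c(100, 100, 100, 0, 0, 0))
  clin <- toy_clinical(c(1, 2, 3, 10, 11, 12), rep(1, 6))
  sw <- sweep_cutoffs(prof, clin, cutoffs = c(0, 5))
  expect_equal(sw$c_index, c(0.8, 0.8))
  expect_equal(sw$n_loss, c(3, 3))
})

test_that("cut-offs with no score variation are flagged undefined", {
  prof <- toy_profiles(c(10, 20, 0, 0))
  clin <- toy_clinical(c(1, 2, 3, 4), rep(1, 4))
  sw <- sweep_cutoffs(prof, clin, cutoffs = c(5, 50, 100))
  expect_equal(sw$n_loss, c(2, 0, 0))
  expect_false(is.na(sw$c_index[1]))
  expect_true(all(is.na(sw$c_index[2:3])))
})

test_that("sweep joins fail loudly on missing samples", {
  prof <- toy_profiles(c(10, 20))
  clin <- toy_clinical(c(1, 2, 3), rep(1, 3))
  expect_error(sweep_cutoffs(prof, clin), "s3")
  expect_error(sweep_cutoffs(prof, clin[1, ]), "clinical")
  two_arms <- rbind(prof, toy_profiles(c(1, 2), arm_label = "chr22q"))
  expect_error(sweep_cutoffs(two_arms, clin[1:2, ]), "one arm")
})

test_that("n_loss is non-increasing and c-index piecewise constant", {
  set.seed(41)
  n <- 120
  lp <- sample(c(0, 0, 0, 3, 8, 40, 100), n, replace = TRUE)
  prof <- toy_profiles(lp)
  clin <- toy_clinical(rexp(n, 0.1), rbinom(n, 1, 0.7))
  sw <- sweep_cutoffs(prof, clin, 0:30)
  expect_true(all(diff(sw$n_loss) <= 0))
  # the c-index can only change where some sample's call flips
  flips <- diff(sw$n_loss) != 0
  same <- diff(sw$c_index) == 0
  expect_true(all(same[!flips]))
})

test_that("cohorts are scored separately, never pooled", {
  prof <- toy_profiles(c(100, 0, 100, 0), ids = c("a1", "a2", "b1", "b2"))
  clin <- toy_clinical(c(1, 9, 2, 8), rep(1, 4),
                       ids = c("a1", "a2", "b1", "b2"),
                       cohort = c("c1", "c1", "c2", "c2"))
  sw <- sweep_cutoffs(prof, clin, cutoffs = 5)
  expect_equal(nrow(sw), 2)
  expect_setequal(sw$cohort, c("c1", "c2"))
  expect_equal(sw$n, c(2, 2))
  expect_equal(sw$c_index, c(1, 1))
  s <- summarize_sweep(sw)
  expect_equal(s$mean_c_index, 1)
})

test_that("stratification reports KM, log-rank and median difference", {
  prof <- toy_profiles(c(rep(100, 5), rep(0, 5)))
  clin <- toy_clinical(c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15), rep(1, 10))
  st <- stratify_by_cutoff(prof, clin, 5)
  expect_s3_class(st, "stratified_analysis")
  expect_equal(st$counts$n, c(5, 5))
  expect_equal(st$groups$loss$median, 3)
  expect_equal(st$groups$no_loss$median, 13)
  expect_equal(st$median_difference, 10)
  expect_lt(st$logrank$p_value, 0.05)
  expect_error(stratify_by_cutoff(prof, clin, 100), "empty group")
})

test_that("cut-off 0 and cut-off 5 differ exactly on the 1-5% cases", {
  lp <- c(0, 1, 3, 5, 6, 20, 100)
  at0 <- apply_cutoff(lp, 0)
  at5 <- apply_cutoff(lp, 5)
  expect_equal(which(at0 & !at5), which(lp >= 1 & lp <= 5))
  expect_equal(at0 != at5, lp >= 1 & lp <= 5)
})

test_that("grade-1 co-loss rule assigns groups per the 5% rule", {
  p1 <- toy_profiles(c(6, 6, 0, 100, 0), arm_label = "chr1p")
  p22 <- toy_profiles(c(40, 0, 40, 100, 0), arm_label = "chr22q")
  clin <- toy_clinical(c(2, 9, 10, 1, 12), c(1, 1, 1, 1, 1))
  g <- grade1_co_loss_analysis(p1, p22, clin, cutoff_percent = 5)
  # 1p 6% + 22q 40% is co-loss; 1p 6% + 22q 0% is single loss
  expect_equal(g$counts$n[g$counts$group == "co_loss"], 2)
  expect_equal(g$counts$n[g$counts$group == "no_or_single"], 3)

  g4 <- grade1_co_loss_analysis(p1, p22, clin, four_group = TRUE)
  expect_setequal(names(g4$by_pattern),
                  c("co_loss", "chr1p_only", "chr22q_only", "none"))

  clin$who_grade <- 2
  expect_error(grade1_co_loss_analysis(p1, p22, clin), "grade 1")
})

test_that("non-grade-1 cases are excluded from the co-loss analysis", {
  p1 <- toy_profiles(c(100, 100, 0, 0, 100))
  p22 <- toy_profiles(c(100, 100, 0, 0, 100))
  clin <- toy_clinical(c(1, 2, 9, 10, 3), rep(1, 5),
                       who_grade = c(1, 1, 1, 1, 3))
  g <- grade1_co_loss_analysis(p1, p22, clin)
  expect_equal(sum(g$counts$n), 4)
})

test_that("null stratification p-values are roughly uniform", {
  # both groups drawn from the same distribution: Monte-Carlo calibration
  set.seed(77)
  pvals <- replicate(400, {
    n <- 60
    prof <- toy_profiles(sample(c(0, 100), n, replace = TRUE,
                                prob = c(0.5, 0.5)))
    clin <- toy_clinical(rexp(n, 0.2), rbinom(n, 1, 0.7))
    stratify_by_cutoff(prof, clin, 5)$logrank$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.2) - 0.2), 0.06)
})
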