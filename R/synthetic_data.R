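#' Configuration for the synthetic meningioma-like cohort simulator
#'
#' Defines the generative model for [simulate_cohort()].  The defaults
#' emulate the structure reported for large meningioma CNV cohorts: a
#' strongly bimodal 1p loss-extent distribution (most cases at 0% or
#' 96-100%), telomere-anchored partial losses, a ~2% rate of spurious
#' focal 1-5% losses in truly intact samples, methylation-class
#' composition shifting from ~94% benign classes at 0% loss to ~72%
#' intermediate/malignant classes at complete loss, frequent 22q co-loss,
#' and exponential recurrence-free survival whose hazard is raised by true
#' 1p loss and further by concurrent 1p/22q loss.
#'
#' @param n_subjects Subjects per cohort.
#' @param n_cohorts Number of independent cohorts (3 = discovery plus two
#'   validation cohorts).
#' @param p_no_loss,p_segmental,p_complete Mixture weights of the three
#'   true 1p extent strata (0%, 6-95% telomere-anchored, 96-100%); must
#'   sum to 1.
#' @param p_artifact Probability that a truly intact sample acquires a
#'   spurious focal measured loss of 1-5% of the arm (the noise/focal-loss
#'   failure mode that motivates a >5% cut-off).
#' @param noise_sd Gaussian standard deviation added to every segment's
#'   log2 ratio.
#' @param loss_log2,gain_log2 Mean log2 ratio of loss / gain segments
#'   (one-copy loss on an impure tumor sits well above -1).
#' @param p_gain Probability of an incidental focal 1p gain (reported by
#'   the profiling but never part of the loss rule).
#' @param baseline_hazard Recurrence hazard per year without 1p loss.
#' @param hr_loss Hazard ratio for true 1p loss (> 5% of the arm).
#' @param hr_co_loss Additional hazard ratio when 1p loss co-occurs with
#'   22q loss.
#' @param censoring_rate Exponential censoring rate per year.
#' @param p_22q_given_loss,p_22q_given_none Probability of whole-arm 22q
#'   loss given presence/absence of true 1p loss.
#' @param mc_mixture 2 x 6 matrix of methylation-class probabilities (rows
#'   `"none"` and `"complete"`, columns [MC_CLASSES]); partial losses
#'   interpolate linearly between the rows by loss extent.
#' @param grade_probs List with elements `no_loss` and `loss`, each a
#'   length-3 probability vector over WHO grades 1-3.
#' @param survival_model `"exponential"` (closed-form medians) or
#'   `"weibull"`.
#' @param weibull_shape Shape parameter when `survival_model = "weibull"`.
#' @param interstitial Place partial losses at a random interior position
#'   instead of anchored at the 1p telomere.
#' @param cytoband Path to the cytoband file defining arm coordinates;
#'   defaults to the bundled synthetic hg19-like file.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration including the seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 500,
                              n_cohorts = 3,
                              p_no_loss = 0.60,
                              p_segmental = 0.10,
                              p_complete = 0.30,
                              p_artifact = 0.02,
                              noise_sd = 0.03,
                              loss_log2 = -0.45,
                              gain_log2 = 0.40,
                              p_gain = 0.03,
                              baseline_hazard = 0.04,
                              hr_loss = 3,
                              hr_co_loss = 2,
                              censoring_rate = 0.05,
                              p_22q_given_loss = 0.80,
                              p_22q_given_none = 0.35,
                              mc_mixture = default_mc_mixture(),
                              grade_probs = list(
                                no_loss = c(0.85, 0.12, 0.03),
                                loss = c(0.55, 0.33, 0.12)),
                              survival_model = c("exponential", "weibull"),
                              weibull_shape = 1.2,
                              interstitial = FALSE,
                              cytoband = NULL,
                              seed = 1L) {
  survival_model <- match.arg(survival_model)
  probs <- c(p_no_loss, p_segmental, p_complete)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("p_no_loss + p_segmental + p_complete must equal 1")
  }
  for (p in c(p_artifact, p_gain, p_22q_given_loss, p_22q_given_none)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (baseline_hazard <= 0 || censoring_rate <= 0 ||
      hr_loss <= 0 || hr_co_loss <= 0) {
    stop("hazard rates and hazard ratios must be positive")
  }
  if (!is.matrix(mc_mixture) || nrow(mc_mixture) != 2L ||
      ncol(mc_mixture) != 6L ||
      any(abs(rowSums(mc_mixture) - 1) > 1e-9) || any(mc_mixture < 0)) {
    stop("mc_mixture must be a 2 x 6 probability matrix with rows summing",
         " to 1 over ", paste(MC_CLASSES, collapse = ", "))
  }
  for (g in grade_probs) {
    if (length(g) != 3L || any(g < 0) || abs(sum(g) - 1) > 1e-9) {
      stop("grade_probs entries must be length-3 probability vectors")
    }
  }
  if (is.null(cytoband)) {
    cytoband <- system.file("extdata", "cytoband_synthetic_hg19like.txt",
                            package = "armloss")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_cohorts = as.integer(n_cohorts),
    p_no_loss = p_no_loss, p_segmental = p_segmental,
    p_complete = p_complete, p_artifact = p_artifact,
    noise_sd = noise_sd, loss_log2 = loss_log2, gain_log2 = gain_log2,
    p_gain = p_gain, baseline_hazard = baseline_hazard,
    hr_loss = hr_loss, hr_co_loss = hr_co_loss,
    censoring_rate = censoring_rate,
    p_22q_given_loss = p_22q_given_loss,
    p_22q_given_none = p_22q_given_none,
    mc_mixture = mc_mixture, grade_probs = grade_probs,
    survival_model = survival_model, weibull_shape = weibull_shape,
    interstitial = interstitial, cytoband = cytoband,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default methylation-class mixture anchors
#'
#' Row `"none"` (0% loss) puts 94% of mass on the three benign classes;
#' row `"complete"` (> 95% loss) puts 72% on the intermediate/malignant
#' classes.  Partial losses interpolate linearly between the rows.
#'
#' @return 2 x 6 probability matrix over [MC_CLASSES].
#' @export
default_mc_mixture <- function() {
  m <- rbind(
    none     = c(0.40, 0.34, 0.20, 0.03, 0.02, 0.01),
    complete = c(0.10, 0.09, 0.09, 0.30, 0.22, 0.20)
  )
  colnames(m) <- MC_CLASSES
  m
}

# Split [start, end) into n_chunks contiguous pieces with noisy log2 means.
chunk_segments <- function(start, end, mean_log2, noise_sd, n_chunks) {
  if (end - start < n_chunks) n_chunks <- 1L
  cuts <- if (n_chunks > 1L) {
    sort(sample.int(end - start - 1L, n_chunks - 1L)) + start
  } else numeric(0)
  s <- c(start, cuts)
  e <- c(cuts, end)
  data.frame(start = s, end = e,
             log2 = stats::rnorm(length(s), mean_log2, noise_sd))
}

#' Simulate a multi-cohort copy-number + survival study
#'
#' Generates, deterministically for a given configuration, segmented
#' copy-number calls on chromosomes 1 and 22 together with a clinical
#' table and the generative truth.  See [simulation_config()] for the
#' model: true 1p loss extent is drawn from a three-component mixture
#' (none / segmental / complete); partial losses are telomere-anchored
#' intervals; spurious focal 1-5% losses are injected in intact samples at
#' rate `p_artifact`; 22q loss is whole-arm with 1p-dependent frequency;
#' recurrence-free times are exponential (or Weibull) with hazard
#' `baseline_hazard * hr_loss^[1p loss] * hr_co_loss^[1p and 22q loss]`
#' and independent exponential censoring; methylation classes follow an
#' extent-interpolated mixture and WHO grade a loss-dependent distribution.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_cohort`: list with `segments` (SEG data model, see
#'   [read_seg()]), `clinical` (see [read_clinical()]), `truth` (per-sample
#'   generative values) and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_subjects = 30,
#'                                             n_cohorts = 1, seed = 42))
#' head(cohort$truth)
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  arms <- load_cytobands(config$cytoband, genome_build = "simulated")
  a1p <- get_arm(arms, "chr1p"); a1q <- get_arm(arms, "chr1q")
  a22p <- get_arm(arms, "chr22p"); a22q <- get_arm(arms, "chr22q")

  n <- config$n_subjects * config$n_cohorts
  ids <- sprintf("S%05d", seq_len(n))
  cohort_names <- if (config$n_cohorts == 3L) {
    c("discovery", "retrospective", "prospective")
  } else {
    paste0("cohort", seq_len(config$n_cohorts))
  }
  cohort <- rep(cohort_names, each = config$n_subjects)

  # one seeded master stream feeding per-phase sub-streams, so a change in
  # one phase's draws leaves the other phases' marginals untouched
  set.seed(config$seed)
  phase_seed <- sample.int(.Machine$integer.max - 1L, 7L)

  # phase 1: true 1p extent strata
  set.seed(phase_seed[1L])
  stratum <- sample(c("none", "segmental", "complete"), n, replace = TRUE,
                    prob = c(config$p_no_loss, config$p_segmental,
                             config$p_complete))
  f_true <- numeric(n)
  f_true[stratum == "segmental"] <-
    stats::runif(sum(stratum == "segmental"), 0.06, 0.95)
  f_true[stratum == "complete"] <-
    stats::runif(sum(stratum == "complete"), 0.96, 1.00)

  # phase 2: spurious focal losses in truly intact samples
  set.seed(phase_seed[2L])
  artifact <- stratum == "none" & stats::runif(n) < config$p_artifact
  artifact_frac <- stats::runif(n, 0.01, 0.05)
  artifact_pos <- stats::runif(n)

  # phase 3: 22q whole-arm loss, co-occurring with 1p loss
  set.seed(phase_seed[3L])
  loss1_true <- f_true > 0.05
  p22 <- ifelse(loss1_true, config$p_22q_given_loss,
                config$p_22q_given_none)
  loss22 <- stats::runif(n) < p22

  # phase 4: recurrence-free survival with proportional hazards
  set.seed(phase_seed[4L])
  hazard <- config$baseline_hazard *
    config$hr_loss^loss1_true *
    config$hr_co_loss^(loss1_true & loss22)
  t_event <- if (config$survival_model == "exponential") {
    stats::rexp(n, rate = hazard)
  } else {
    k <- config$weibull_shape
    stats::rweibull(n, shape = k, scale = (1 / hazard)^(1 / k))
  }
  t_censor <- stats::rexp(n, rate = config$censoring_rate)
  time <- pmin(t_event, t_censor)
  event <- as.numeric(t_event <= t_censor)

  # phase 5: methylation class, interpolated by extent
  set.seed(phase_seed[5L])
  mc_class <- character(n)
  for (i in seq_len(n)) {
    pr <- (1 - f_true[i]) * config$mc_mixture["none", ] +
      f_true[i] * config$mc_mixture["complete", ]
    mc_class[i] <- sample(MC_CLASSES, 1L, prob = pr)
  }

  # phase 6: WHO grade
  set.seed(phase_seed[6L])
  who_grade <- numeric(n)
  for (i in seq_len(n)) {
    pr <- if (loss1_true[i]) config$grade_probs$loss
          else config$grade_probs$no_loss
    who_grade[i] <- sample(1:3, 1L, prob = pr)
  }

  # phase 7: measured segments with log2 noise
  set.seed(phase_seed[7L])
  seg_list <- vector("list", n)
  gain_draw <- stats::runif(n)
  for (i in seq_len(n)) {
    rows <- list()
    L <- a1p$length
    k_loss <- round(f_true[i] * L)
    if (k_loss > 0) {
      if (config$interstitial && k_loss < L) {
        off <- floor(stats::runif(1L) * (L - k_loss))
      } else {
        off <- 0
      }
      ls <- a1p$start + off
      rows[[length(rows) + 1L]] <-
        chunk_segments(ls, ls + k_loss, config$loss_log2, config$noise_sd,
                       sample(1:2, 1L))
      if (off > 0) {
        rows[[length(rows) + 1L]] <-
          chunk_segments(a1p$start, ls, 0, config$noise_sd, 1L)
      }
      if (ls + k_loss < a1p$end) {
        rows[[length(rows) + 1L]] <-
          chunk_segments(ls + k_loss, a1p$end, 0, config$noise_sd,
                         sample(1:3, 1L))
      }
    } else {
      rows[[length(rows) + 1L]] <-
        chunk_segments(a1p$start, a1p$end, 0, config$noise_sd,
                       sample(2:4, 1L))
    }
    if (artifact[i]) {
      alen <- max(1, round(artifact_frac[i] * L))
      astart <- a1p$start + floor(artifact_pos[i] * (L - alen))
      rows[[length(rows) + 1L]] <-
        data.frame(start = astart, end = astart + alen,
                   log2 = stats::rnorm(1L, config$loss_log2,
                                       config$noise_sd))
    }
    if (gain_draw[i] < config$p_gain) {
      glen <- round(stats::runif(1L, 0.05, 0.20) * L)
      gstart <- a1p$start + floor(stats::runif(1L) * (L - glen))
      rows[[length(rows) + 1L]] <-
        data.frame(start = gstart, end = gstart + glen,
                   log2 = stats::rnorm(1L, config$gain_log2,
                                       config$noise_sd))
    }
    seg_1p <- do.call(rbind, rows)
    seg_1p$chrom <- a1p$chrom
    seg_1q <- chunk_segments(a1q$start, a1q$end, 0, config$noise_sd,
                             sample(1:3, 1L))
    seg_1q$chrom <- a1q$chrom
    seg_22p <- chunk_segments(a22p$start, a22p$end, 0, config$noise_sd, 1L)
    seg_22p$chrom <- a22p$chrom
    seg_22q <- chunk_segments(a22q$start, a22q$end,
                              if (loss22[i]) config$loss_log2 else 0,
                              config$noise_sd, sample(1:2, 1L))
    seg_22q$chrom <- a22q$chrom
    seg <- rbind(seg_1p, seg_1q, seg_22p, seg_22q)
    seg$sample_id <- ids[i]
    seg_list[[i]] <- seg
  }
  seg <- do.call(rbind, seg_list)
  segments <- data.frame(
    sample_id = seg$sample_id,
    chrom = seg$chrom,
    start = seg$start,
    end = seg$end,
    n_probes = pmax(2, round((seg$end - seg$start) / 5e4)),
    log2_ratio = seg$log2,
    stringsAsFactors = FALSE
  )
  rownames(segments) <- NULL

  clinical <- data.frame(
    sample_id = ids, time = time, event = event, who_grade = who_grade,
    mc_class = mc_class, cohort = cohort, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    sample_id = ids, cohort = cohort, stratum = stratum,
    true_loss_fraction_1p = f_true,
    true_loss_percent_1p = percent_from_bases(round(f_true * a1p$length),
                                              a1p$length),
    artifact_1p = artifact,
    loss_1p = loss1_true, loss_22q = loss22,
    co_loss = loss1_true & loss22,
    hazard = hazard,
    stringsAsFactors = FALSE
  )
  structure(list(segments = segments, clinical = clinical, truth = truth,
                 config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated study: ", nrow(x$clinical), " subjects in ",
      x$config$n_cohorts, " cohort(s); ", nrow(x$segments),
      " CNV segments\n", sep = "")
  cat("True 1p extent strata:\n")
  print(table(x$truth$stratum))
  invisible(x)
}

#' Compare pipeline output against simulation truth
#'
#' Closes the parameter-recovery loop: given a simulated cohort and the 1p
#' arm profiles computed from its segments, reports (i) the confusion
#' matrix and accuracy of the cut-off loss call against true loss, (ii)
#' observed vs closed-form group medians (exponential model), and (iii)
#' the observed concordance of the call vs the analytic concordance of the
#' two-group exponential model without censoring
#' (w * h/(1+h) + (1-w) * 0.5, with h the loss hazard ratio and w the
#' comparable cross-pair fraction).
#'
#' @param cohort A `simulated_cohort`.
#' @param profiles 1p arm profiles computed from `cohort$segments` by
#'   [arm_profiles()].
#' @param cutoff_percent Cut-off for the loss call.
#' @return A `truth_recovery_report` list: `confusion` (2 x 2 table,
#'   called x true), `accuracy`, `c_index` (`concordance_result`),
#'   `expected_c_index`, `observed_medians`, `expected_medians`,
#'   `median_difference`, `expected_median_difference`.
#' @export
truth_recovery_report <- function(cohort, profiles, cutoff_percent = 5) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  idx <- match(cohort$truth$sample_id, profiles$sample_id)
  if (anyNA(idx)) {
    stop("profiles are missing sample(s): ",
         paste(cohort$truth$sample_id[is.na(idx)], collapse = ", "))
  }
  called <- apply_cutoff(profiles$loss_percent[idx], cutoff_percent)
  truth <- apply_cutoff(cohort$truth$true_loss_percent_1p, cutoff_percent)
  confusion <- table(called = called, truth = truth)
  accuracy <- mean(called == truth)
  cl <- cohort$clinical
  ci <- harrell_cindex(cl$time, cl$event, as.numeric(called))
  cfg <- cohort$config
  n1 <- sum(truth); n0 <- sum(!truth); n <- n1 + n0
  h <- cfg$hr_loss
  w <- 2 * n1 * n0 / (n * (n - 1))
  expected_c <- w * h / (1 + h) + (1 - w) * 0.5
  km_loss <- km_fit(cl$time[called], cl$event[called])
  km_none <- km_fit(cl$time[!called], cl$event[!called])
  exp_med <- c(loss = log(2) / (cfg$baseline_hazard * cfg$hr_loss),
               no_loss = log(2) / cfg$baseline_hazard)
  structure(list(
    cutoff_percent = cutoff_percent,
    confusion = confusion,
    accuracy = accuracy,
    c_index = ci,
    expected_c_index = expected_c,
    observed_medians = c(loss = km_loss$median, no_loss = km_none$median),
    expected_medians = exp_med,
    median_difference = km_median_difference(km_loss, km_none),
    expected_median_difference = unname(exp_med["no_loss"] -
                                          exp_med["loss"])
  ), class = "truth_recovery_report")
}

#' @export
print.truth_recovery_report <- function(x, ...) {
  cat("Truth recovery at cut-off ", x$cutoff_percent, "%\n", sep = "")
  print(x$confusion)
  cat(sprintf("  call accuracy: %.3f\n", x$accuracy))
  cat(sprintf("  c-index: %.3f (analytic no-censoring reference %.3f)\n",
              x$c_index$c_index, x$expected_c_index))
  cat(sprintf(
    "  median RFS (loss / no loss): %s / %s years (closed form %.1f / %.1f)\n",
    format(x$observed_medians[["loss"]]),
    format(x$observed_medians[["no_loss"]]),
    x$expected_medians[["loss"]], x$expected_medians[["no_loss"]]))
  invisible(x)
}
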