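# Join one arm's profiles onto the clinical table, erroring on samples
# missing from either side.
join_profiles <- function(profiles, records, what = "profiles") {
  if (length(unique(profiles$arm_label)) > 1L) {
    stop("profiles span several arms; supply one arm at a time")
  }
  miss_p <- setdiff(records$sample_id, profiles$sample_id)
  miss_r <- setdiff(profiles$sample_id, records$sample_id)
  if (length(miss_p)) {
    stop("samples missing from ", what, ": ", paste(miss_p, collapse = ", "))
  }
  if (length(miss_r)) {
    stop("samples missing from clinical table: ",
         paste(miss_r, collapse = ", "))
  }
  idx <- match(records$sample_id, profiles$sample_id)
  cbind(records,
        loss_percent = profiles$loss_percent[idx],
        extent_category = profiles$extent_category[idx],
        stringsAsFactors = FALSE)
}

#' Sweep loss-percentage cut-offs scored by concordance index
#'
#' For each cohort and each candidate cut-off c, samples are split by
#' [apply_cutoff()] (loss percent strictly above c) and the dichotomous
#' call is scored against recurrence-free survival with
#' [harrell_cindex()].  Cohorts are never pooled: each contributes its own
#' concordance curve.  Cut-offs at which a cohort has no loss-called or no
#' non-loss samples carry no discrimination and are reported as `NA`.
#'
#' @param profiles Arm-profile data frame for a single arm
#'   (see [arm_profiles()]).
#' @param records Clinical data frame (see [read_clinical()]); joined to
#'   profiles on `sample_id`, with `cohort` defining the strata.
#' @param cutoffs Integer cut-offs to evaluate (default 0-30, spanning the
#'   historically debated 5% vs 30% range).
#' @return A `sweep_result` data frame: `cutoff`, `cohort`, `n`, `n_loss`,
#'   `c_index`.
#' @export
sweep_cutoffs <- function(profiles, records, cutoffs = 0:30) {
  if (any(cutoffs < 0 | cutoffs > 100)) stop("cut-offs must lie in [0, 100]")
  dat <- join_profiles(profiles, records)
  cohorts <- unique(dat$cohort)
  rows <- list()
  k <- 0L
  for (co in cohorts) {
    d <- dat[dat$cohort == co, ]
    for (cc in sort(unique(as.integer(cutoffs)))) {
      called <- apply_cutoff(d$loss_percent, cc)
      ci <- NA_real_
      if (any(called) && !all(called)) {
        ci <- harrell_cindex(d$time, d$event, as.numeric(called))$c_index
      }
      k <- k + 1L
      rows[[k]] <- data.frame(cutoff = cc, cohort = co, n = nrow(d),
                              n_loss = sum(called), c_index = ci,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "arm_label") <- profiles$arm_label[1L]
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Mean concordance across cohorts per cut-off
#'
#' @param sweep A `sweep_result` from [sweep_cutoffs()].
#' @return Data frame `cutoff`, `mean_c_index` (mean over cohorts with a
#'   defined value; `NA` when undefined in every cohort).
#' @export
summarize_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  agg <- tapply(sweep$c_index, sweep$cutoff,
                function(x) if (all(is.na(x))) NA_real_
                            else mean(x, na.rm = TRUE))
  data.frame(cutoff = as.integer(names(agg)),
             mean_c_index = as.numeric(agg))
}

#' Stratify survival at a loss cut-off
#'
#' Splits samples into loss vs no-loss at the given cut-off, fits a
#' Kaplan-Meier curve per group, and compares them with the log-rank test
#' and the difference in median recurrence-free time.
#'
#' @param profiles Arm-profile data frame for one arm.
#' @param records Clinical data frame.
#' @param cutoff_percent Loss-percentage cut-off (loss called when
#'   strictly above).
#' @return A `stratified_analysis`: list with `rule`, `groups` (named list
#'   of `km_curve`s: `"loss"`, `"no_loss"`), `logrank`
#'   (`logrank_result`), `median_difference` (years or `NA`), `counts`.
#' @export
stratify_by_cutoff <- function(profiles, records, cutoff_percent = 5) {
  dat <- join_profiles(profiles, records)
  called <- apply_cutoff(dat$loss_percent, cutoff_percent)
  if (!any(called) || all(called)) {
    stop("cut-off ", cutoff_percent,
         " leaves an empty group; cannot stratify")
  }
  g_loss <- dat[called, ]
  g_none <- dat[!called, ]
  km_loss <- km_fit(g_loss$time, g_loss$event)
  km_none <- km_fit(g_none$time, g_none$event)
  structure(list(
    rule = sprintf("%s loss percent > %d vs <= %d",
                   profiles$arm_label[1L], cutoff_percent, cutoff_percent),
    cutoff_percent = cutoff_percent,
    groups = list(loss = km_loss, no_loss = km_none),
    logrank = logrank_test(dat$time, dat$event,
                           ifelse(called, "loss", "no_loss")),
    median_difference = km_median_difference(km_loss, km_none),
    counts = data.frame(group = c("loss", "no_loss"),
                        n = c(nrow(g_loss), nrow(g_none)),
                        n_events = c(km_loss$n_events, km_none$n_events))
  ), class = "stratified_analysis")
}

#' @export
print.stratified_analysis <- function(x, ...) {
  cat("Stratified survival analysis:", x$rule, "\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("  log-rank chi-square = %.4g, p = %.4g\n",
              x$logrank$statistic, x$logrank$p_value))
  md <- x$median_difference
  cat("  median difference: ",
      if (is.na(md)) "undefined (a median was not reached)"
      else sprintf("%.2f years", md), "\n", sep = "")
  invisible(x)
}

#' Concurrent two-arm loss analysis within WHO grade 1
#'
#' Restricted to histological CNS WHO grade 1 cases, splits subjects into
#' those with concurrent loss of both arms (each called at the same
#' cut-off, by default 5%, i.e. a loss of 6% or more of each arm) versus
#' those with no or a single arm loss, and compares recurrence-free
#' survival.
#'
#' @param profiles_1p,profiles_22q Arm-profile data frames for the two
#'   arms (conventionally chr1p and chr22q).
#' @param records Clinical data frame with `who_grade`.
#' @param cutoff_percent Cut-off applied to both arms.
#' @param four_group Also attach per-pattern Kaplan-Meier curves
#'   (`none`, first arm only, second arm only, co-loss).
#' @return A `stratified_analysis` with groups `co_loss` and
#'   `no_or_single`; when `four_group = TRUE` a `by_pattern` element holds
#'   the four curves.
#' @export
grade1_co_loss_analysis <- function(profiles_1p, profiles_22q, records,
                                    cutoff_percent = 5,
                                    four_group = FALSE) {
  d1 <- join_profiles(profiles_1p, records, "first-arm profiles")
  lbl1 <- profiles_1p$arm_label[1L]
  lbl2 <- profiles_22q$arm_label[1L]
  idx2 <- match(records$sample_id, profiles_22q$sample_id)
  if (anyNA(idx2)) {
    stop("samples missing from second-arm profiles: ",
         paste(records$sample_id[is.na(idx2)], collapse = ", "))
  }
  d1$loss_percent_2 <- profiles_22q$loss_percent[idx2]
  dat <- d1[!is.na(d1$who_grade) & d1$who_grade == 1, ]
  if (nrow(dat) == 0L) stop("no WHO grade 1 subjects in the clinical table")
  loss1 <- apply_cutoff(dat$loss_percent, cutoff_percent)
  loss2 <- apply_cutoff(dat$loss_percent_2, cutoff_percent)
  co <- loss1 & loss2
  if (!any(co) || all(co)) {
    stop("co-loss split leaves an empty group among grade 1 cases")
  }
  g_co <- dat[co, ]
  g_rest <- dat[!co, ]
  km_co <- km_fit(g_co$time, g_co$event)
  km_rest <- km_fit(g_rest$time, g_rest$event)
  out <- structure(list(
    rule = sprintf(
      "WHO grade 1: concurrent %s and %s loss (> %d%%) vs no or single loss",
      lbl1, lbl2, cutoff_percent),
    cutoff_percent = cutoff_percent,
    groups = list(co_loss = km_co, no_or_single = km_rest),
    logrank = logrank_test(dat$time, dat$event,
                           ifelse(co, "co_loss", "no_or_single")),
    median_difference = km_median_difference(km_co, km_rest),
    counts = data.frame(group = c("co_loss", "no_or_single"),
                        n = c(nrow(g_co), nrow(g_rest)),
                        n_events = c(km_co$n_events, km_rest$n_events))
  ), class = "stratified_analysis")
  if (four_group) {
    pat <- ifelse(loss1 & loss2, "co_loss",
                  ifelse(loss1, paste0(lbl1, "_only"),
                         ifelse(loss2, paste0(lbl2, "_only"), "none")))
    out$by_pattern <- lapply(split(dat, pat),
                             function(d) km_fit(d$time, d$event))
  }
  out
}
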