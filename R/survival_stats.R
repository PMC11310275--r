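# Pull (time, event) vectors out of either a clinical data frame or a pair
# of vectors; used by all survival entry points.
surv_inputs <- function(time, event) {
  if (is.data.frame(time)) {
    df <- time
    if (!all(c("time", "event") %in% names(df))) {
      stop("data frame input needs 'time' and 'event' columns")
    }
    time <- df$time
    event <- df$event
  }
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(is.na(time)) || any(time < 0)) {
    stop("times must be non-negative and non-missing")
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  list(time = as.numeric(time), event = as.numeric(event))
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival (recurrence-free) function under right censoring:
#' S(t) is the product over event times t_i <= t of (1 - d_i / n_i), where
#' d_i is the number of events and n_i the number at risk at t_i.  Subjects
#' censored at a time are still at risk for events at that same time
#' (events precede censorings at ties, the textbook convention).
#'
#' @param time Numeric vector of follow-up times (years), or a clinical
#'   data frame with `time` and `event` columns.
#' @param event Event indicator (1 = event, 0 = censored); ignored when
#'   `time` is a data frame.
#' @return A `km_curve`: list with `table` (data frame over distinct
#'   observed times: `time`, `n_risk`, `n_event`, `n_censor`, `survival`),
#'   `median` (smallest event time with S(t) <= 0.5, `NA` when the curve
#'   never reaches 0.5), `n` and `n_events`.
#' @export
#' @examples
#' km <- km_fit(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' km$median
km_fit <- function(time, event = NULL) {
  inp <- surv_inputs(time, event)
  n <- length(inp$time)
  if (n == 0L) stop("km_fit needs at least one subject")
  tt <- sort(unique(inp$time))
  n_event <- vapply(tt, function(t) sum(inp$time == t & inp$event == 1), 0)
  n_censor <- vapply(tt, function(t) sum(inp$time == t & inp$event == 0), 0)
  n_risk <- vapply(tt, function(t) sum(inp$time >= t), 0)
  surv <- cumprod(1 - ifelse(n_risk > 0, n_event / n_risk, 0))
  tab <- data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  ev <- tab$n_event > 0
  med_idx <- which(ev & tab$survival <= 0.5)
  median <- if (length(med_idx)) tab$time[med_idx[1L]] else NA_real_
  structure(list(table = tab, median = median, n = n,
                 n_events = sum(inp$event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", x$n, " subjects, ", x$n_events, " events\n",
      sep = "")
  cat("Median time: ",
      if (is.na(x$median)) "not reached" else format(x$median), "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation: S(t) equals the estimate at the largest
#' observed time <= t, and 1 before the first observed time.
#'
#' @param curve A `km_curve` from [km_fit()].
#' @param times Numeric vector of times.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  idx <- findInterval(times, curve$table$time)
  ifelse(idx == 0L, 1, curve$table$survival[pmax(idx, 1L)])
}

#' Difference between two Kaplan-Meier medians
#'
#' @param group_a,group_b `km_curve` objects.
#' @return Absolute difference of medians in years, or `NA` when either
#'   median is undefined (curve plateaus above 0.5).
#' @export
km_median_difference <- function(group_a, group_b) {
  stopifnot(inherits(group_a, "km_curve"), inherits(group_b, "km_curve"))
  if (is.na(group_a$median) || is.na(group_b$median)) return(NA_real_)
  abs(group_a$median - group_b$median)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test: at each distinct event time the
#' observed number of events in the first group is compared with its
#' hypergeometric expectation given the risk sets, and the squared sum of
#' differences is scaled by the summed hypergeometric variance.  The
#' statistic is chi-squared with 1 degree of freedom under the null; the
#' p-value is its upper tail (no continuity correction).
#'
#' @param time Follow-up times, or a clinical data frame with `time` and
#'   `event` (then `event` is the grouping argument).
#' @param event Event indicators.
#' @param group Vector with exactly two distinct values assigning subjects
#'   to groups.
#' @return A `logrank_result`: list with `statistic`, `p_value`,
#'   `observed`, `expected` (length-2, in group-level order), `groups`.
#' @export
#' @examples
#' logrank_test(c(1, 2, 3, 8, 9, 10), c(1, 1, 1, 1, 1, 0),
#'              c("a", "a", "a", "b", "b", "b"))
logrank_test <- function(time, event = NULL, group = NULL) {
  if (is.data.frame(time) && is.null(group)) {
    group <- event
    event <- NULL
  }
  if (is.null(group)) stop("grouping vector required")
  inp <- surv_inputs(time, event)
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2L) {
    stop("log-rank test requires exactly two groups, found ", length(lev))
  }
  if (length(group) != length(inp$time)) stop("group length mismatch")
  if (sum(inp$event) == 0) stop("log-rank test requires at least one event")
  g1 <- group == lev[1L]
  ev_times <- sort(unique(inp$time[inp$event == 1]))
  o_minus_e <- 0
  v_sum <- 0
  o1 <- 0; e1 <- 0
  for (t in ev_times) {
    at_risk <- inp$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(inp$time == t & inp$event == 1)
    d1 <- sum(inp$time == t & inp$event == 1 & g1)
    e <- d * n1 / n
    o1 <- o1 + d1
    e1 <- e1 + e
    o_minus_e <- o_minus_e + (d1 - e)
    if (n > 1) {
      v_sum <- v_sum + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v_sum <= 0) {
    warning("log-rank variance is zero; no comparable event structure")
    stat <- 0
    p <- 1
  } else {
    stat <- o_minus_e^2 / v_sum
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(statistic = stat, p_value = p,
                 observed = c(o1, sum(inp$event) - o1),
                 expected = c(e1, sum(inp$event) - e1),
                 groups = lev),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test (", x$groups[1L], " vs ", x$groups[2L], ")\n", sep = "")
  cat(sprintf("  chi-square = %.4g on 1 df, p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Harrell's concordance index
#'
#' The probability, over comparable subject pairs, that the subject with
#' the higher risk score experiences the event earlier.  A pair is
#' comparable when the subject with the strictly smaller observed time had
#' an event, or when times are tied and exactly one subject had an event
#' (the event then precedes the censoring).  Pairs tied on time with both
#' events, or with the shorter time censored, carry no ranking information
#' and are omitted.  Comparable pairs with tied scores contribute 1/2.
#'
#' @param time Follow-up times, or a clinical data frame with `time` and
#'   `event` columns (then `event` is the score argument).
#' @param event Event indicators.
#' @param score Numeric risk scores, higher = higher predicted risk.  A
#'   logical vector (e.g. a loss call) is accepted.
#' @return A `concordance_result`: list with `c_index`, `n_concordant`,
#'   `n_discordant`, `n_tied_score`, `n_comparable`.
#' @export
#' @examples
#' harrell_cindex(c(1, 2, 3), c(1, 1, 1), score = c(3, 2, 1))
harrell_cindex <- function(time, event = NULL, score = NULL) {
  if (is.data.frame(time) && is.null(score)) {
    score <- event
    event <- NULL
  }
  inp <- surv_inputs(time, event)
  if (is.null(score)) stop("a risk score is required")
  score <- as.numeric(score)
  n <- length(inp$time)
  if (length(score) != n) stop("score length mismatch")
  if (any(is.na(score))) stop("scores must be non-missing")
  conc <- 0; disc <- 0; tied <- 0
  t <- inp$time; e <- inp$event
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    ti <- t[i]; tj <- t[j]
    # index of the "earlier" subject in each comparable pair
    i_first <- (ti < tj & e[i] == 1) | (ti == tj & e[i] == 1 & e[j] == 0)
    j_first <- (tj < ti & e[j] == 1) | (ti == tj & e[j] == 1 & e[i] == 0)
    s_first <- ifelse(i_first, score[i], score[j])
    s_other <- ifelse(i_first, score[j], score[i])
    comp <- i_first | j_first
    conc <- conc + sum(comp & s_first > s_other)
    disc <- disc + sum(comp & s_first < s_other)
    tied <- tied + sum(comp & s_first == s_other)
  }
  n_comp <- conc + disc + tied
  if (n_comp == 0) stop("c-index undefined: no comparable pairs")
  structure(list(c_index = (conc + 0.5 * tied) / n_comp,
                 n_concordant = conc, n_discordant = disc,
                 n_tied_score = tied, n_comparable = n_comp),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Harrell c-index = %.4f (%d concordant / %d discordant / %d score-tied of %d comparable pairs)\n",
    x$c_index, x$n_concordant, x$n_discordant, x$n_tied_score,
    x$n_comparable))
  invisible(x)
}

#' Export a Kaplan-Meier curve as a plain table
#'
#' Writes `time`, `survival`, `n_risk`, `n_event`, `n_censor` as TSV for
#' downstream plotting.
#'
#' @param curve A `km_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.table(
    curve$table[, c("time", "survival", "n_risk", "n_event", "n_censor")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
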