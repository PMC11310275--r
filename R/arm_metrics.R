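#' Copy-number call thresholds
#'
#' A segment is called a loss when its log2 copy-ratio is strictly below
#' `loss_log2` and a gain when strictly above `gain_log2`; otherwise it is
#' neutral.  Methylation-array CNV pipelines leave this threshold to the
#' analyst; the +/- 0.15 default is a common heuristic for array-derived
#' log2 ratios and should be revisited for strongly contaminated samples.
#'
#' @param loss_log2 Loss threshold (negative).
#' @param gain_log2 Gain threshold (positive).
#' @return A `call_thresholds` object.
#' @export
call_thresholds <- function(loss_log2 = -0.15, gain_log2 = 0.15) {
  if (!is.numeric(loss_log2) || !is.numeric(gain_log2) ||
      !(loss_log2 < 0 && 0 < gain_log2)) {
    stop("thresholds must satisfy loss_log2 < 0 < gain_log2")
  }
  structure(list(loss_log2 = loss_log2, gain_log2 = gain_log2),
            class = "call_thresholds")
}

#' Call the copy-number state of segments
#'
#' @param log2_ratio Numeric vector of segment log2 copy-ratios.
#' @param thresholds A [call_thresholds()] object.
#' @return Character vector in `{"loss", "neutral", "gain"}`.  Both
#'   comparisons are strict, so a segment exactly at a threshold is
#'   neutral.
#' @export
#' @examples
#' call_segment_state(c(-0.4, 0, -0.15, 0.3))
call_segment_state <- function(log2_ratio, thresholds = call_thresholds()) {
  stopifnot(inherits(thresholds, "call_thresholds"))
  ifelse(log2_ratio < thresholds$loss_log2, "loss",
         ifelse(log2_ratio > thresholds$gain_log2, "gain", "neutral"))
}

# Round to integer percent, half away from zero, using exact integer
# arithmetic when the fraction is bases/len (both integral): avoids the
# usual floating-point drift at .5 boundaries.
percent_from_bases <- function(bases, len) {
  as.integer(floor((200 * bases + len) / (2 * len)))
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Classify arm-loss extent
#'
#' Arm loss is `"complete"` when more than 95% of the arm is deleted,
#' `"segmental"` when more than 5% and at most 95% is deleted, and
#' `"none"` at 5% or below.
#'
#' @param loss_percent Integer percent in 0-100 (vectorized).
#' @return Character vector in `{"none", "segmental", "complete"}`.
#' @export
#' @examples
#' classify_extent(c(0, 5, 6, 95, 96, 100))
classify_extent <- function(loss_percent) {
  if (any(loss_percent < 0 | loss_percent > 100, na.rm = TRUE)) {
    stop("loss_percent must lie in [0, 100]")
  }
  ifelse(loss_percent > 95, "complete",
         ifelse(loss_percent > 5, "segmental", "none"))
}

#' Apply a loss-percentage cut-off
#'
#' A sample is called "arm loss" at cut-off c when its loss percentage
#' strictly exceeds c; at the recommended 5% cut-off this counts cases
#' with a loss percentage of 6% or higher.
#'
#' @param loss_percent Integer percent in 0-100 (vectorized).
#' @param cutoff_percent Cut-off in 0-100.
#' @return Logical vector: loss called.
#' @export
#' @examples
#' apply_cutoff(c(0, 5, 6, 100), cutoff_percent = 5)
apply_cutoff <- function(loss_percent, cutoff_percent) {
  if (length(cutoff_percent) != 1L || is.na(cutoff_percent) ||
      cutoff_percent < 0 || cutoff_percent > 100) {
    stop("cutoff_percent must be a single value in [0, 100]")
  }
  loss_percent > cutoff_percent
}

# Resolve overlapping same-sample segments on one arm and return the
# per-state base counts.  Elementary-interval sweep: between consecutive
# breakpoints the covering segment with the largest |log2| wins (ties break
# toward the smaller, i.e. more loss-like, log2) — deterministic and
# order-independent.
resolve_arm_bases <- function(start, end, log2_ratio, arm_start, arm_end,
                              thresholds) {
  s <- pmax(start, arm_start)
  e <- pmin(end, arm_end)
  keep <- s < e
  s <- s[keep]; e <- e[keep]; v <- log2_ratio[keep]
  counts <- c(loss = 0, neutral = 0, gain = 0)
  if (length(s) == 0L) {
    counts["neutral"] <- arm_end - arm_start
    return(counts)
  }
  bp <- sort(unique(c(s, e)))
  a <- bp[-length(bp)]
  b <- bp[-1L]
  for (k in seq_along(a)) {
    cov <- which(s <= a[k] & e >= b[k])
    if (length(cov) == 0L) {
      counts["neutral"] <- counts["neutral"] + (b[k] - a[k])
      next
    }
    vv <- v[cov]
    best <- vv[order(-abs(vv), vv)][1L]
    st <- call_segment_state(best, thresholds)
    counts[st] <- counts[st] + (b[k] - a[k])
  }
  # arm territory before the first / after the last breakpoint is neutral;
  # interior gaps are uncovered elementary intervals, counted above
  counts["neutral"] <- counts["neutral"] +
    (arm_end - arm_start) - (bp[length(bp)] - bp[1L])
  counts
}

#' Per-arm loss/gain fractions for one sample
#'
#' Computes the fraction of an arm's bases covered by loss-called and
#' gain-called segments for a single sample.  Coordinates are 0-based
#' half-open; segments are clipped to the arm; arm territory not covered by
#' any segment counts as neutral.  Overlapping same-sample segments are
#' resolved per base by the most extreme log2 ratio (largest absolute
#' value; ties go to the lower, loss-side value), which is deterministic
#' and independent of row order.
#'
#' With `weight = "probe"` fractions are probe-weighted instead: each
#' segment contributes its probe count, allocated to the arm in proportion
#' to its overlap, and the denominator is the total probes allocated to the
#' arm (uncovered territory then carries no weight).  Overlaps are not
#' resolved in probe space; probe weighting requires `n_probes` on every
#' contributing segment.
#'
#' @param segments Segment data frame (see [read_seg()]) for one sample;
#'   rows on other chromosomes are ignored.
#' @param arm One-row arm slice from [get_arm()].
#' @param thresholds A [call_thresholds()] object.
#' @param weight `"base"` (genomic extent, default) or `"probe"`.
#' @return One-row data frame: `sample_id`, `chrom`, `arm`, `arm_label`,
#'   `loss_fraction`, `gain_fraction`, `neutral_fraction`, `loss_percent`
#'   (integer, rounded half away from zero), `extent_category`.
#' @export
arm_fractions <- function(segments, arm, thresholds = call_thresholds(),
                          weight = c("base", "probe")) {
  weight <- match.arg(weight)
  stopifnot(nrow(arm) == 1L, arm$length > 0)
  sid <- unique(segments$sample_id)
  if (length(sid) > 1L) {
    stop("arm_fractions expects segments of a single sample; found ",
         length(sid), " sample ids (use arm_profiles for cohorts)")
  }
  if (length(sid) == 0L) sid <- NA_character_
  seg <- segments[segments$chrom == arm$chrom &
                    segments$end > arm$start & segments$start < arm$end, ,
                  drop = FALSE]
  if (weight == "base") {
    counts <- resolve_arm_bases(seg$start, seg$end, seg$log2_ratio,
                                arm$start, arm$end, thresholds)
    loss_frac <- counts[["loss"]] / arm$length
    gain_frac <- counts[["gain"]] / arm$length
    lp <- percent_from_bases(counts[["loss"]], arm$length)
  } else {
    if (nrow(seg) == 0L) {
      stop("probe weighting is undefined with no segments on the arm")
    }
    if (any(is.na(seg$n_probes))) {
      stop("probe weighting requires n_probes on every segment")
    }
    ov <- intersect_length(seg$start, seg$end, arm)
    w <- seg$n_probes * ov / (seg$end - seg$start)
    st <- call_segment_state(seg$log2_ratio, thresholds)
    tot <- sum(w)
    loss_frac <- sum(w[st == "loss"]) / tot
    gain_frac <- sum(w[st == "gain"]) / tot
    lp <- round_half_up(100 * loss_frac)
  }
  data.frame(
    sample_id = sid,
    chrom = arm$chrom,
    arm = arm$arm,
    arm_label = arm$arm_label,
    loss_fraction = loss_frac,
    gain_fraction = gain_frac,
    neutral_fraction = 1 - loss_frac - gain_frac,
    loss_percent = lp,
    extent_category = classify_extent(lp),
    stringsAsFactors = FALSE
  )
}

#' Per-sample, per-arm profiles for a cohort
#'
#' Applies [arm_fractions()] to every sample in a segment table, for one or
#' more arms.
#'
#' @param segments Segment data frame for any number of samples.
#' @param arm_table An `arm_table` from [load_cytobands()].
#' @param arms Character vector of arm labels (e.g. `c("chr1p", "chr22q")`).
#' @param thresholds A [call_thresholds()] object.
#' @param weight See [arm_fractions()].
#' @return Data frame with one row per sample x arm, columns as in
#'   [arm_fractions()]; `call_thresholds` and `genome_build` attributes
#'   record provenance.
#' @export
#' @examples
#' cyto <- system.file("extdata", "cytoband_synthetic_hg19like.txt",
#'                     package = "armloss")
#' arms <- load_cytobands(cyto)
#' cohort <- simulate_cohort(simulation_config(n_subjects = 20,
#'                                             n_cohorts = 1, seed = 7))
#' head(arm_profiles(cohort$segments, arms, "chr1p"))
arm_profiles <- function(segments, arm_table, arms = "chr1p",
                         thresholds = call_thresholds(),
                         weight = c("base", "probe")) {
  weight <- match.arg(weight)
  samples <- unique(segments$sample_id)
  by_sample <- split(seq_len(nrow(segments)), segments$sample_id)
  out <- vector("list", length(samples) * length(arms))
  k <- 0L
  for (lbl in arms) {
    arm <- get_arm(arm_table, lbl)
    for (sid in samples) {
      k <- k + 1L
      out[[k]] <- arm_fractions(segments[by_sample[[sid]], , drop = FALSE],
                                arm, thresholds, weight)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "call_thresholds") <- thresholds
  attr(res, "genome_build") <- attr(arm_table, "genome_build")
  res
}

#' Bin a cohort's loss-percentage distribution
#'
#' Bins integer loss percentages with 0% isolated in its own bin and
#' subsequent bins left-open right-closed, e.g. width 5 gives bins 0, 1-5,
#' 6-10, ..., 96-100.  Optionally attaches the per-bin composition over
#' the six methylation classes.
#'
#' @param profiles Arm-profile data frame (one arm) from [arm_profiles()],
#'   or an integer vector of loss percents.
#' @param bin_width Bin width in percent; must divide 100.
#' @param mc_labels Optional named character vector mapping `sample_id` to
#'   methylation class, or a clinical data frame with `sample_id` and
#'   `mc_class` columns.
#' @return A `binned_distribution` data frame: `bin` (label), `lower`,
#'   `upper` (closed integer-percent bounds), `count`, and, when
#'   `mc_labels` is given, one composition column per class (per-bin
#'   fractions summing to 1 in non-empty bins).
#' @export
#' @examples
#' bin_distribution(c(0L, 0L, 3L, 97L), bin_width = 5)
bin_distribution <- function(profiles, bin_width = 5, mc_labels = NULL) {
  if (is.data.frame(profiles)) {
    if (length(unique(profiles$arm_label)) > 1L) {
      stop("profiles span several arms; bin one arm at a time")
    }
    lp <- profiles$loss_percent
    ids <- profiles$sample_id
  } else {
    lp <- as.integer(profiles)
    ids <- names(profiles)
  }
  if (100 %% bin_width != 0) stop("bin_width must divide 100")
  if (any(lp < 0 | lp > 100)) stop("loss percents must lie in [0, 100]")
  nb <- 100 %/% bin_width
  lower <- c(0L, seq.int(1L, by = bin_width, length.out = nb))
  upper <- c(0L, seq.int(bin_width, by = bin_width, length.out = nb))
  label <- ifelse(lower == upper, as.character(lower),
                  paste0(lower, "-", upper))
  idx <- as.integer(ifelse(lp == 0L, 1L, 1L + ceiling(lp / bin_width)))
  count <- tabulate(idx, nbins = nb + 1L)
  out <- data.frame(bin = label, lower = lower, upper = upper,
                    count = count, stringsAsFactors = FALSE)
  if (!is.null(mc_labels)) {
    if (is.data.frame(mc_labels)) {
      mc_labels <- stats::setNames(mc_labels$mc_class, mc_labels$sample_id)
    }
    if (is.null(ids)) {
      stop("methylation-class composition needs sample ids on the profiles")
    }
    missing_ids <- setdiff(ids, names(mc_labels))
    if (length(missing_ids)) {
      stop("no methylation class for sample(s): ",
           paste(missing_ids, collapse = ", "))
    }
    mc <- mc_labels[ids]
    bad <- which(!mc %in% MC_CLASSES)
    if (length(bad)) {
      stop("unknown mc_class '", mc[bad[1L]], "'; permitted labels: ",
           paste(MC_CLASSES, collapse = ", "))
    }
    for (cls in MC_CLASSES) {
      n_cls <- tabulate(idx[mc == cls], nbins = nb + 1L)
      out[[cls]] <- ifelse(count > 0L, n_cls / count, 0)
    }
  }
  class(out) <- c("binned_distribution", "data.frame")
  out
}
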