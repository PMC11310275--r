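# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately share no code with the package internals:
# the per-base labeler paints every base, the concordance oracle walks all
# ordered pairs with scalar logic.

# Label every base of [arm_start, arm_end): for each base the covering
# segment with the largest |log2| wins (ties -> smaller log2), uncovered
# bases are neutral; then count states.
per_base_counts <- function(start, end, log2, arm_start, arm_end,
                            loss_log2 = -0.15, gain_log2 = 0.15) {
  L <- arm_end - arm_start
  best_abs <- rep(-1, L)
  best_val <- rep(Inf, L)
  for (k in seq_along(start)) {
    s <- max(start[k], arm_start)
    e <- min(end[k], arm_end)
    if (s >= e) next
    idx <- (s - arm_start + 1):(e - arm_start)
    v <- log2[k]
    av <- abs(v)
    repl <- idx[av > best_abs[idx] |
                  (av == best_abs[idx] & v < best_val[idx])]
    best_abs[repl] <- av
    best_val[repl] <- v
  }
  covered <- best_abs >= 0
  state <- rep("neutral", L)
  state[covered & best_val < loss_log2] <- "loss"
  state[covered & best_val > gain_log2] <- "gain"
  c(loss = sum(state == "loss"),
    neutral = sum(state == "neutral"),
    gain = sum(state == "gain"))
}

# Exhaustive ordered-pair concordance count with Harrell comparability:
# subject i is the "earlier" member when t_i < t_j with an event, or at a
# tied time when i has the event and j is censored.
cindex_oracle <- function(time, event, score) {
  n <- length(time)
  conc <- 0; disc <- 0; tied <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <-
        (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!comparable) next
      if (score[i] > score[j]) {
        conc <- conc + 1
      } else if (score[i] < score[j]) {
        disc <- disc + 1
      } else {
        tied <- tied + 1
      }
    }
  }
  ncomp <- conc + disc + tied
  list(c_index = if (ncomp > 0) (conc + 0.5 * tied) / ncomp else NA_real_,
       n_concordant = conc, n_discordant = disc, n_tied_score = tied,
       n_comparable = ncomp)
}

# Random segment set on a toy arm, with overlaps and flanking overhang.
random_toy_segments <- function(arm_len, n_seg, sample_id = "s1") {
  start <- sample.int(arm_len + 200L, n_seg, replace = TRUE) - 101L
  len <- sample.int(max(2L, arm_len %/% 2L), n_seg, replace = TRUE)
  data.frame(
    sample_id = sample_id,
    chrom = "chr1",
    start = start,
    end = start + len,
    n_probes = NA_real_,
    log2_ratio = sample(c(-0.6, -0.3, -0.15, -0.05, 0, 0.05, 0.15, 0.3),
                        n_seg, replace = TRUE) +
      stats::rnorm(n_seg, 0, 0.02),
    stringsAsFactors = FALSE
  )
}

# One-row arm slice without going through a cytoband file.
toy_arm <- function(start, end, chrom = "chr1", arm = "p") {
  out <- data.frame(chrom = chrom, arm = arm,
                    arm_label = paste0(chrom, arm),
                    start = start, end = end, length = end - start,
                    stringsAsFactors = FALSE)
  class(out) <- c("arm_table", "data.frame")
  out
}

# Small random survival cohort with ties (times on a coarse grid).
random_surv_cohort <- function(n, tie_grid = 12L, p_event = 0.6,
                               score_levels = 4L) {
  data.frame(
    time = sample.int(tie_grid, n, replace = TRUE) / 2,
    event = stats::rbinom(n, 1L, p_event),
    score = sample.int(score_levels, n, replace = TRUE)
  )
}

write_toy_cytoband <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

bundled_cytoband <- function() {
  system.file("extdata", "cytoband_synthetic_hg19like.txt",
              package = "armloss")
}
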