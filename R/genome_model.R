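#' Normalize chromosome names to UCSC style
#'
#' Accepts `"1"` or `"chr1"` and canonicalizes to `"chr1"`.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector with a `"chr"` prefix.
#' @export
#' @examples
#' normalize_chrom(c("1", "chr22", "X"))
normalize_chrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Load chromosome-arm coordinates from a UCSC-style cytoband file
#'
#' Parses a cytoband file (5 tab-separated columns, no header: chromosome,
#' start, end, band name, Giemsa stain; 0-based half-open coordinates) and
#' collapses the bands of each chromosome into p- and q-arm intervals: an
#' arm's start is the minimum start of its bands and its end the maximum
#' end.  Centromeric (`acen`) bands belong to the arm their name starts
#' with, so for a chromosome with both arms the p-arm end equals the q-arm
#' start.  Acrocentric chromosomes whose file lists only one arm keep just
#' that arm's entry.
#'
#' @param path Path to the cytoband file.
#' @param genome_build Label recorded on the result for provenance
#'   (e.g. `"hg19"`); the file itself carries no build information.
#' @return An `arm_table`: a data frame with one row per chromosome arm and
#'   columns `chrom`, `arm` (`"p"`/`"q"`), `arm_label` (e.g. `"chr1p"`),
#'   `start`, `end`, `length`, plus a `genome_build` attribute.
#' @export
#' @examples
#' cyto <- system.file("extdata", "cytoband_synthetic_hg19like.txt",
#'                     package = "armloss")
#' arms <- load_cytobands(cyto, genome_build = "hg19-like-synthetic")
#' arms[arms$arm_label == "chr1p", ]
load_cytobands <- function(path, genome_build = "unknown") {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("no bands parsed from '", path, "'")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    i <- which(nf < 5L)[1L]
    stop("malformed cytoband line ", line_no[i],
         ": expected 5 tab-separated fields, found ", nf[i])
  }
  chrom <- normalize_chrom(vapply(fields, `[[`, "", 1L))
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  band  <- vapply(fields, `[[`, "", 4L)
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1L]
    stop("malformed cytoband line ", line_no[i], ": non-numeric coordinate")
  }
  arm <- substr(band, 1L, 1L)
  if (!all(arm %in% c("p", "q"))) {
    i <- which(!arm %in% c("p", "q"))[1L]
    stop("malformed cytoband line ", line_no[i],
         ": band name '", band[i], "' does not begin with 'p' or 'q'")
  }
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    stop("malformed cytoband line ", line_no[i], ": start >= end")
  }

  key <- paste(chrom, arm, sep = "\r")
  arm_start <- tapply(start, key, min)
  arm_end   <- tapply(end,   key, max)
  ks <- strsplit(names(arm_start), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(ks, `[[`, "", 1L),
    arm   = vapply(ks, `[[`, "", 2L),
    start = as.numeric(arm_start),
    end   = as.numeric(arm_end),
    stringsAsFactors = FALSE
  )
  out$arm_label <- paste0(out$chrom, out$arm)
  out$length <- out$end - out$start
  # stable ordering: by chromosome (file order of first appearance), p then q
  out <- out[order(match(out$chrom, unique(chrom)), out$arm), ]
  rownames(out) <- NULL

  # shared centromere boundary when both arms present
  for (cc in unique(out$chrom)) {
    sub <- out[out$chrom == cc, ]
    if (nrow(sub) == 2L) {
      p <- sub[sub$arm == "p", ]
      q <- sub[sub$arm == "q", ]
      if (p$end != q$start) {
        stop("chromosome ", cc, ": p-arm end (", p$end,
             ") does not meet q-arm start (", q$start,
             "); bands leave a gap or overlap at the centromere")
      }
    }
  }
  out <- out[, c("chrom", "arm", "arm_label", "start", "end", "length")]
  attr(out, "genome_build") <- genome_build
  class(out) <- c("arm_table", "data.frame")
  out
}

#' Look up one arm in an arm table
#'
#' @param arm_table An `arm_table` from [load_cytobands()].
#' @param arm_label Arm label such as `"chr1p"`; `"1p"` is accepted.
#' @return A one-row `arm_table` slice.
#' @export
get_arm <- function(arm_table, arm_label) {
  stopifnot(inherits(arm_table, "arm_table"))
  lbl <- ifelse(grepl("^chr", arm_label), arm_label, paste0("chr", arm_label))
  i <- match(lbl, arm_table$arm_label)
  if (is.na(i)) {
    stop("arm '", lbl, "' not found; available: ",
         paste(arm_table$arm_label, collapse = ", "))
  }
  arm_table[i, , drop = FALSE]
}

#' Overlap length between a segment and an arm interval
#'
#' All coordinates are 0-based half-open; the result is the number of bases
#' of `[seg_start, seg_end)` that fall inside the arm interval, 0 when
#' disjoint.  Vectorized over segments.
#'
#' @param seg_start,seg_end Segment coordinates (`seg_start < seg_end`).
#' @param arm A one-row arm slice (from [get_arm()]) or any list with
#'   numeric `start` and `end`.
#' @return Numeric vector of overlap lengths in bases.
#' @export
intersect_length <- function(seg_start, seg_end, arm) {
  if (any(seg_start >= seg_end)) {
    stop("segment start must be < end")
  }
  pmax(0, pmin(seg_end, arm$end[1L]) - pmax(seg_start, arm$start[1L]))
}
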