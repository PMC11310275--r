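#' Read segmented copy-number calls (IGV SEG dialect)
#'
#' Reads a tab-separated SEG file with a header line and columns sample,
#' chromosome, start, end, optionally number of probes, and segment mean
#' (log2 copy-ratio), in that order; column names are not interpreted
#' beyond counting them.  Coordinates are canonicalized to 0-based
#' half-open; set `coords = "one_based"` for files whose start column is
#' 1-based inclusive (e.g. DNAcopy-style output).  Row order is preserved.
#'
#' @param path Path to the SEG file.
#' @param coords Coordinate basis of the file: `"zero_based"` (half-open,
#'   default) or `"one_based"` (closed intervals; start is shifted down by
#'   one on input).
#' @return A data frame of segments with columns `sample_id`, `chrom`,
#'   `start`, `end`, `n_probes` (NA when the file has no probe column) and
#'   `log2_ratio`.
#' @seealso [write_seg()]
#' @export
read_seg <- function(path, coords = c("zero_based", "one_based")) {
  coords <- match.arg(coords)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty SEG file: '", path, "'")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  ncol <- length(header)
  if (!ncol %in% c(5L, 6L)) {
    stop("SEG schema error: expected 5 or 6 tab-separated columns ",
         "(sample, chrom, start, end, [num probes,] seg mean), found ", ncol)
  }
  has_probes <- ncol == 6L
  body <- lines[-1L]
  if (length(body) == 0L) {
    return(empty_segments())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != ncol)) {
    i <- which(nf != ncol)[1L]
    stop("SEG parse error at line ", i + 1L, ": expected ", ncol,
         " fields, found ", nf[i])
  }
  col <- function(j) vapply(fields, `[[`, "", j)
  num <- function(j, what, allow_na = FALSE) {
    raw <- col(j)
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & !(allow_na & !nzchar(trimws(raw)))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("SEG parse error at line ", i + 1L, ": non-numeric ", what,
           " '", raw[i], "'")
    }
    v
  }
  seg <- data.frame(
    sample_id = col(1L),
    chrom = normalize_chrom(col(2L)),
    start = num(3L, "start"),
    end = num(4L, "end"),
    n_probes = if (has_probes) num(5L, "probe count", allow_na = TRUE)
               else NA_real_,
    log2_ratio = num(if (has_probes) 6L else 5L, "seg mean"),
    stringsAsFactors = FALSE
  )
  if (coords == "one_based") seg$start <- seg$start - 1
  validate_segments(seg, line_offset = 1L)
  seg
}

empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start = numeric(), end = numeric(),
             n_probes = numeric(), log2_ratio = numeric(),
             stringsAsFactors = FALSE)
}

#' Validate a segment data frame
#'
#' Checks the segment data model: `start < end`, finite log2 ratio, and
#' positive probe counts where present.  Called by [read_seg()] and
#' [write_seg()]; exported so externally constructed segment tables can be
#' checked too.
#'
#' @param segments Data frame with the columns of [read_seg()]'s output.
#' @param line_offset Internal; added to row numbers in error messages.
#' @return `segments`, invisibly, if valid.
#' @export
validate_segments <- function(segments, line_offset = 0L) {
  req <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  miss <- setdiff(req, names(segments))
  if (length(miss)) {
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  }
  where <- function(i) paste0("row ", i + line_offset)
  bad <- which(!(segments$start < segments$end))
  if (length(bad)) {
    stop("invalid segment at ", where(bad[1L]), ": start (",
         segments$start[bad[1L]], ") must be < end (",
         segments$end[bad[1L]], ")")
  }
  bad <- which(!is.finite(segments$log2_ratio))
  if (length(bad)) {
    stop("invalid segment at ", where(bad[1L]), ": log2 ratio is not finite")
  }
  if ("n_probes" %in% names(segments)) {
    np <- segments$n_probes
    bad <- which(!is.na(np) & np <= 0)
    if (length(bad)) {
      stop("invalid segment at ", where(bad[1L]),
           ": probe count must be positive")
    }
  }
  invisible(segments)
}

#' Write segments to an IGV SEG file
#'
#' Emits the standard tab-separated SEG layout (`ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`); the probe column is omitted when no
#' segment carries a probe count.  `read_seg(write_seg(x))` is the identity
#' on the data model.
#'
#' @param segments Segment data frame as returned by [read_seg()].
#' @param path Output path.
#' @param coords Coordinate basis to emit; `"one_based"` shifts starts up
#'   by one.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, coords = c("zero_based", "one_based")) {
  coords <- match.arg(coords)
  if (nrow(segments) > 0L) validate_segments(segments)
  has_probes <- "n_probes" %in% names(segments) &&
    any(!is.na(segments$n_probes))
  start <- segments$start + if (coords == "one_based") 1 else 0
  cols <- list(segments$sample_id, segments$chrom,
               format_coord(start), format_coord(segments$end))
  header <- c("ID", "chrom", "loc.start", "loc.end")
  if (has_probes) {
    cols <- c(cols, list(ifelse(is.na(segments$n_probes), "",
                                format_coord(segments$n_probes))))
    header <- c(header, "num.mark")
  }
  # %.17g round-trips doubles exactly through the text format
  cols <- c(cols, list(sprintf("%.17g", segments$log2_ratio)))
  header <- c(header, "seg.mean")
  body <- do.call(paste, c(cols, sep = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = "\t"), body), con)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a clinical/survival table
#'
#' Reads a tab- or comma-separated table (delimiter chosen from the file
#' extension: `.csv` means comma, anything else tab) with a header and at
#' least the columns `sample_id`, `time` (recurrence-free time) and `event`
#' (1 = recurrence, 0 = censored).  Optional columns: `who_grade` (1-3),
#' `mc_class` (one of [MC_CLASSES]) and `cohort` (defaults to
#' `"cohort1"`).
#'
#' @param path Path to the table.
#' @param time_unit Unit of the `time` column; `"months"` values are
#'   converted to years on input (all downstream analyses work in years).
#' @return A data frame of subject records with columns `sample_id`,
#'   `time` (years), `event`, `who_grade`, `mc_class`, `cohort`.
#' @export
read_clinical <- function(path, time_unit = c("years", "months")) {
  time_unit <- match.arg(time_unit)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  req <- c("sample_id", "time", "event")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("clinical table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  rec <- data.frame(
    sample_id = as.character(tab$sample_id),
    time = as.numeric(tab$time),
    event = as.numeric(tab$event),
    who_grade = if ("who_grade" %in% names(tab)) as.numeric(tab$who_grade)
                else NA_real_,
    mc_class = if ("mc_class" %in% names(tab)) as.character(tab$mc_class)
               else NA_character_,
    cohort = if ("cohort" %in% names(tab)) as.character(tab$cohort)
             else "cohort1",
    stringsAsFactors = FALSE
  )
  if (time_unit == "months") rec$time <- rec$time / 12
  validate_clinical(rec)
  rec
}

#' Validate a clinical table
#'
#' Enforces the subject-record invariants: non-negative time, event in
#' \{0, 1\}, WHO grade in \{1, 2, 3\} when present, and methylation class
#' among the six permitted labels when present.
#'
#' @param records Data frame as returned by [read_clinical()].
#' @return `records`, invisibly, if valid.
#' @export
validate_clinical <- function(records) {
  bad <- which(is.na(records$time) | records$time < 0)
  if (length(bad)) {
    stop("invalid clinical row ", bad[1L],
         ": time must be a non-negative number")
  }
  bad <- which(!records$event %in% c(0, 1))
  if (length(bad)) {
    stop("invalid clinical row ", bad[1L], ": event must be 0 or 1, found ",
         records$event[bad[1L]])
  }
  g <- records$who_grade
  bad <- which(!is.na(g) & !g %in% c(1, 2, 3))
  if (length(bad)) {
    stop("invalid clinical row ", bad[1L], ": who_grade must be 1, 2 or 3")
  }
  mc <- records$mc_class
  bad <- which(!is.na(mc) & !mc %in% MC_CLASSES)
  if (length(bad)) {
    stop("invalid clinical row ", bad[1L], ": unknown mc_class '",
         mc[bad[1L]], "'; permitted labels: ",
         paste(MC_CLASSES, collapse = ", "))
  }
  invisible(records)
}

#' Write a clinical table
#'
#' Tab-separated counterpart to [read_clinical()]; times are written in
#' years.
#'
#' @param records Clinical data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(records, path) {
  validate_clinical(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
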