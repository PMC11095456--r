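# BED / bedGraph readers returning GenomicRanges objects.
#
# BED coordinates are 0-based half-open; GRanges are 1-based closed. The
# conversion (start + 1) at the I/O boundary preserves half-open overlap
# semantics exactly: BED [0,100) and [100,200) do not overlap, and neither
# do GRanges 1..100 and 101..200.

#' Read genomic intervals from a BED file
#'
#' Accepts BED3 to BED6; `name` and `score` columns are preserved as
#' metadata when present. Validation is strict: fewer than 3 columns,
#' `end <= start`, or a negative start is a fatal error naming the line.
#'
#' @param path Path to a BED file. Ignored when `text` is given.
#' @param text Optional character scalar of BED-formatted text.
#' @return A [GenomicRanges::GRanges] object.
#' @export
read_bed <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3L))
    stopf("BED format error: fewer than 3 columns at line %d",
          which(n_col < 3L)[1L])
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end))
    stopf("BED format error: non-numeric coordinate at line %d",
          which(is.na(start) | is.na(end))[1L])
  if (any(start < 0))
    stopf("BED format error: negative start at line %d", which(start < 0)[1L])
  if (any(end <= start))
    stopf("BED format error: end <= start at line %d",
          which(end <= start)[1L])
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1, end = end))
  if (any(n_col >= 4L)) {
    S4Vectors::mcols(gr)$name <- vapply(fields, function(f)
      if (length(f) >= 4L) f[[4L]] else NA_character_, character(1))
  }
  if (any(n_col >= 5L)) {
    S4Vectors::mcols(gr)$score <- vapply(fields, function(f)
      if (length(f) >= 5L) suppressWarnings(as.numeric(f[[5L]])) else
        NA_real_, numeric(1))
  }
  gr
}

#' Write genomic intervals to a BED file
#'
#' @param gr A `GRanges` object; `name`/`score` metadata columns are written
#'   when present.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) {
    df$name <- mc$name
    if ("score" %in% names(mc)) df$score <- mc$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Parses 4-column bedGraph text into a `coverage_track`: piecewise-constant
#' non-negative coverage with implicit zero outside the listed intervals.
#' Overlapping intervals within a chromosome and non-numeric values are
#' fatal errors.
#'
#' @param path Path to a bedGraph file. Ignored when `text` is given.
#' @param text Optional character scalar of bedGraph-formatted text.
#' @return An object of class `coverage_track`: list with `gr` (GRanges with
#'   a `value` column) and `library_size` (sum of value times width).
#' @export
read_bedgraph <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(coverage_track(GenomicRanges::GRanges(value = numeric())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L))
    stopf("bedGraph format error: fewer than 4 columns at line %d",
          which(lengths(fields) < 4L)[1L])
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  if (anyNA(start) || anyNA(end) || any(start < 0) || any(end <= start))
    stopf("bedGraph format error: bad interval at line %d",
          which(is.na(start) | is.na(end) | start < 0 | end <= start)[1L])
  if (anyNA(value))
    stopf("bedGraph format error: non-numeric value at line %d",
          which(is.na(value))[1L])
  if (any(value < 0))
    stopf("bedGraph format error: negative coverage at line %d",
          which(value < 0)[1L])
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start + 1, end = end),
                               value = value)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits) > 0L)
    stopf("bedGraph format error: overlapping intervals at lines %d and %d",
          S4Vectors::queryHits(hits)[1L], S4Vectors::subjectHits(hits)[1L])
  coverage_track(gr)
}

#' @noRd
coverage_track <- function(gr) {
  lib <- sum(gr$value * GenomicRanges::width(gr))
  structure(list(gr = gr, library_size = lib), class = "coverage_track")
}

#' Write a coverage track to a bedGraph file
#'
#' @param track A `coverage_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- track$gr
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   value = gr$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d intervals, library size %.4g\n",
              length(x$gr), x$library_size))
  invisible(x)
}
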