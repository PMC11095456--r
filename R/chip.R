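# Peak-anchored ChIP signal quantification and correlation.
#
# Peaks become fixed-width windows (peak centre +/- flank, the +/-1000 bp
# convention of peak-centred heatmaps); coverage tracks are integrated over
# each window, normalized to counts-per-million of track library size,
# winsorized for display, and compared across tracks by ordinary least
# squares on log10(signal + pseudocount).

#' Build peak-anchored windows
#'
#' `center` mode (default, heatmap-compatible) produces equal-width windows
#' `[mid - flank, mid + flank)` around each peak midpoint; `edges` mode
#' widens each peak by `flank` on both sides (variable width). Windows
#' running past a chromosome boundary (or below position 0) are dropped,
#' not truncated, so heatmap rows keep equal width; the number dropped is
#' attached as attribute `n_dropped`.
#'
#' @param peaks `GRanges` of peaks ([read_bed()]).
#' @param flank Flank size in bp (> 0).
#' @param mode `"center"` or `"edges"`.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return `GRanges` of windows, in input order.
#' @export
make_windows <- function(peaks, flank = 1000L,
                         mode = c("center", "edges"), chrom_sizes = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(flank) || flank <= 0) stopf("flank must be positive")
  start0 <- GenomicRanges::start(peaks) - 1  # 0-based
  end0 <- GenomicRanges::end(peaks)
  if (mode == "center") {
    mid <- floor((start0 + end0) / 2)
    ws <- mid - flank
    we <- mid + flank
  } else {
    ws <- start0 - flank
    we <- end0 + flank
  }
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  keep <- ws >= 0
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[chrom]
    keep <- keep & !is.na(len) & we <= len
  }
  out <- GenomicRanges::GRanges(chrom[keep],
                                IRanges::IRanges(start = ws[keep] + 1,
                                                 end = we[keep]))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Integrate track coverage over windows
#'
#' Per window, the integral of the piecewise-constant coverage over the
#' half-open window (sum of value times overlap width). Windows on
#' chromosomes absent from the track count 0 (with a warning).
#'
#' @param track A `coverage_track` ([read_bedgraph()]).
#' @param windows `GRanges` of windows.
#' @return Numeric vector of counts, one per window.
#' @export
count_windows <- function(track, windows) {
  stopifnot(inherits(track, "coverage_track"))
  counts <- numeric(length(windows))
  if (length(track$gr) == 0L || length(windows) == 0L) return(counts)
  missing_chr <- setdiff(unique(as.character(
    GenomicRanges::seqnames(windows))),
    unique(as.character(GenomicRanges::seqnames(track$gr))))
  if (length(missing_chr))
    warning("window chromosome(s) absent from track: ",
            paste(missing_chr, collapse = ", "), call. = FALSE)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(windows, track$gr))
  if (length(hits) == 0L) return(counts)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(GenomicRanges::end(windows)[qh],
             GenomicRanges::end(track$gr)[sh]) -
    pmax(GenomicRanges::start(windows)[qh],
         GenomicRanges::start(track$gr)[sh]) + 1
  contrib <- ov * track$gr$value[sh]
  agg <- rowsum(contrib, qh)
  counts[as.integer(rownames(agg))] <- agg[, 1]
  counts
}

#' Window-by-track count matrix
#'
#' @param tracks Named list of `coverage_track`s.
#' @param windows `GRanges` of windows.
#' @return Object of class `window_count_matrix`: list with `raw`
#'   (windows x tracks), `library_sizes`, `windows`.
#' @export
count_matrix <- function(tracks, windows) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  raw <- vapply(tracks, count_windows, numeric(length(windows)),
                windows = windows)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = length(windows),
                                       dimnames = list(NULL, names(tracks)))
  libs <- vapply(tracks, `[[`, numeric(1), "library_size")
  structure(list(raw = raw, library_sizes = libs, windows = windows),
            class = "window_count_matrix")
}

#' Library-size (CPM) normalization of a count matrix
#'
#' `normalized(w, t) = raw(w, t) * 1e6 / library_size(t)`, so doubling a
#' track's coverage everywhere leaves its normalized column unchanged.
#'
#' @param x A `window_count_matrix`.
#' @param factors Optional user-supplied normalization factors (named per
#'   track) replacing the library sizes.
#' @return The matrix object with a `normalized` element added.
#' @export
normalize_counts <- function(x, factors = NULL) {
  stopifnot(inherits(x, "window_count_matrix"))
  libs <- if (is.null(factors)) x$library_sizes else factors[colnames(x$raw)]
  if (any(!is.finite(libs) | libs <= 0))
    stopf("zero or invalid library size for track(s): %s",
          paste(colnames(x$raw)[!is.finite(libs) | libs <= 0],
                collapse = ", "))
  x$normalized <- sweep(x$raw, 2L, 1e6 / libs, `*`)
  x
}

#' Log-log regression between two tracks
#'
#' Ordinary least squares of `log10(y + pseudocount)` on
#' `log10(x + pseudocount)` over windows, with the Pearson correlation of
#' the transformed values.
#'
#' @param x A `window_count_matrix` (normalized if available) or a plain
#'   numeric matrix.
#' @param track_x,track_y Column names or indices.
#' @param pseudocount Added before the log transform.
#' @return List with `slope`, `intercept`, `r`, `n`.
#' @export
correlate_tracks <- function(x, track_x, track_y, pseudocount = 1) {
  mat <- if (inherits(x, "window_count_matrix")) {
    if (!is.null(x$normalized)) x$normalized else x$raw
  } else x
  xv <- log10(mat[, track_x] + pseudocount)
  yv <- log10(mat[, track_y] + pseudocount)
  if (length(xv) < 3L) stopf("need at least 3 windows")
  mx <- mean(xv)
  my <- mean(yv)
  sxx <- sum((xv - mx)^2)
  if (sxx == 0) stopf("zero variance in track '%s'", as.character(track_x))
  sxy <- sum((xv - mx) * (yv - my))
  syy <- sum((yv - my)^2)
  slope <- sxy / sxx
  list(slope = slope, intercept = my - slope * mx,
       r = if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy),
       n = length(xv))
}

#' Winsorize a matrix at global percentiles
#'
#' Values above the `upper_pct` percentile (linear-interpolation
#' definition, [stats::quantile()] type 7) are set to that percentile, and
#' symmetrically for `lower_pct`; percentiles are computed over the whole
#' matrix, matching the single colour scale of a heatmap
#' ("overexposure").
#'
#' @param mat Numeric matrix or vector.
#' @param upper_pct Upper percentile in (0, 100].
#' @param lower_pct Lower percentile in [0, 100).
#' @return Winsorized matrix of the same shape.
#' @export
winsorize <- function(mat, upper_pct = 99, lower_pct = 0) {
  stopifnot(lower_pct < upper_pct, upper_pct <= 100, lower_pct >= 0)
  hi <- stats::quantile(mat, upper_pct / 100, names = FALSE, type = 7)
  lo <- stats::quantile(mat, lower_pct / 100, names = FALSE, type = 7)
  mat[mat > hi] <- hi
  mat[mat < lo] <- lo
  mat
}

#' Overlap stratification of two peak sets
#'
#' Flags each peak in `peaks_a` that overlaps (by at least 1 bp, half-open
#' semantics) any peak in `peaks_b` — e.g. CTBP2 peaks stratified by
#' whether they coincide with an EVI1 binding site.
#'
#' @param peaks_a,peaks_b `GRanges` of peaks.
#' @return List with `flag` (logical per peak of `peaks_a`) and `fraction`
#'   (flagged / total).
#' @export
overlap_stratify <- function(peaks_a, peaks_b) {
  flag <- GenomicRanges::countOverlaps(peaks_a, peaks_b) > 0
  list(flag = flag,
       fraction = if (length(flag)) mean(flag) else NA_real_)
}

#' Ranked, winsorized heatmap matrix
#'
#' Rows (windows) sorted by descending signal in the ranking track, ties
#' broken by window coordinate (chrom, start); winsorization is applied
#' after ranking so the displayed order reflects the raw signal.
#'
#' @param x A `window_count_matrix` (normalized if available).
#' @param rank_by_track Column name or index of the ranking track.
#' @param upper_pct,lower_pct Winsorization percentiles.
#' @return List with `matrix` (ordered, winsorized) and `order` (row
#'   permutation applied).
#' @export
rank_heatmap_matrix <- function(x, rank_by_track, upper_pct = 99,
                                lower_pct = 0) {
  stopifnot(inherits(x, "window_count_matrix"))
  mat <- if (!is.null(x$normalized)) x$normalized else x$raw
  chrom <- as.character(GenomicRanges::seqnames(x$windows))
  start <- GenomicRanges::start(x$windows)
  ord <- order(-mat[, rank_by_track], chrom, start)
  list(matrix = winsorize(mat[ord, , drop = FALSE], upper_pct, lower_pct),
       order = ord)
}
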