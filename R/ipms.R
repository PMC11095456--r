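# Label-free IP-MS differential enrichment.
#
# The input is a proteins x samples matrix of log2 LFQ intensities with NA
# for missing values and a two-group sample assignment. The workflow is:
# group-validity filtering, missing-value imputation, per-protein Welch t
# test with a permutation-based FDR (group labels permuted, 250 rounds by
# default), and volcano-style significance calling (|log2FC| and raw p, the
# convention of enrichment volcanoes) or FDR-based calling.

#' Construct an intensity matrix
#'
#' @param mat Numeric proteins x samples matrix, `NA` = missing; rownames
#'   are protein ids, colnames sample ids.
#' @param groups Named character vector mapping every sample to a group.
#' @return Object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(mat, groups) {
  stopifnot(is.matrix(mat), !is.null(colnames(mat)))
  if (nrow(mat) > 0L && is.null(rownames(mat)))
    stopf("intensity matrix needs protein ids as rownames")
  if (!all(colnames(mat) %in% names(groups)))
    stopf("sample(s) without a group: %s",
          paste(setdiff(colnames(mat), names(groups)), collapse = ", "))
  groups <- groups[colnames(mat)]
  structure(list(mat = mat, groups = groups), class = "intensity_matrix")
}

#' Read a log2 intensity TSV and sample sheet
#'
#' @param path TSV with first column protein id, remaining columns one per
#'   sample (header row), empty/`NA` cells missing.
#' @param sample_sheet TSV with columns `sample`, `group`.
#' @return An `intensity_matrix`.
#' @export
read_intensity_matrix <- function(path, sample_sheet) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  ss <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  intensity_matrix(mat, stats::setNames(ss$group, ss$sample))
}

#' Write an intensity matrix and sample sheet to TSV
#'
#' @param x An `intensity_matrix`.
#' @param path Matrix TSV path.
#' @param sample_sheet Optional sample-sheet TSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(x, path, sample_sheet = NULL) {
  df <- data.frame(protein = rownames(x$mat), x$mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet)) {
    utils::write.table(data.frame(sample = names(x$groups),
                                  group = unname(x$groups)),
                       sample_sheet, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Filter proteins on per-group valid-value counts
#'
#' Retains proteins quantified (non-missing) in at least `min_valid`
#' samples of at least one group (`any_group`, the default) or of every
#' group (`each_group`).
#'
#' @param x An `intensity_matrix`.
#' @param min_valid Minimum valid values per group.
#' @param scope `"any_group"` or `"each_group"`.
#' @return Filtered `intensity_matrix`.
#' @export
filter_valid <- function(x, min_valid = 3L,
                         scope = c("any_group", "each_group")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "intensity_matrix"))
  glev <- unique(x$groups)
  sizes <- table(x$groups)
  if (min_valid > max(sizes))
    stopf("min_valid (%d) exceeds the largest group size (%d)",
          min_valid, max(sizes))
  counts <- vapply(glev, function(g)
    rowSums(!is.na(x$mat[, x$groups == g, drop = FALSE])), numeric(nrow(x$mat)))
  keep <- if (scope == "any_group") apply(counts >= min_valid, 1L, any)
          else apply(counts >= min_valid, 1L, all)
  intensity_matrix(x$mat[keep, , drop = FALSE], x$groups)
}

#' Impute missing intensities
#'
#' Strategies mirror common proteomics practice for left-censored
#' missingness: `below_min` replaces every missing value by the global
#' observed minimum minus `shift`; `fixed` by a constant; `min_prob` draws
#' from a normal distribution centred below the observed minimum
#' (`Normal(min - downshift * sd, (width * sd)^2)`, seeded).
#'
#' @param x An `intensity_matrix`.
#' @param strategy `"below_min"`, `"fixed"` or `"min_prob"`.
#' @param shift Downshift for `below_min` (log2 units).
#' @param value Constant for `fixed`.
#' @param width,downshift `min_prob` scale and centre parameters, in units
#'   of the observed standard deviation.
#' @param seed RNG seed for `min_prob`.
#' @return Imputed `intensity_matrix` (no missing values).
#' @export
impute_missing <- function(x, strategy = c("below_min", "fixed", "min_prob"),
                           shift = 0.5, value = NULL, width = 0.3,
                           downshift = 1.8, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(x, "intensity_matrix"))
  mat <- x$mat
  miss <- is.na(mat)
  if (!any(miss)) return(x)
  if (strategy != "fixed" && all(miss))
    stopf("cannot impute an all-missing matrix with strategy '%s'", strategy)
  if (strategy == "below_min") {
    mat[miss] <- min(mat, na.rm = TRUE) - shift
  } else if (strategy == "fixed") {
    if (is.null(value)) stopf("strategy 'fixed' requires `value`")
    mat[miss] <- value
  } else {
    obs_sd <- stats::sd(mat[!miss])
    centre <- min(mat, na.rm = TRUE) - downshift * obs_sd
    set.seed(seed)
    mat[miss] <- stats::rnorm(sum(miss), mean = centre, sd = width * obs_sd)
  }
  intensity_matrix(mat, x$groups)
}

#' Welch t statistics for a two-group matrix
#'
#' @noRd
welch_t <- function(mat, is_a, s0 = 0) {
  n1 <- sum(is_a)
  n2 <- sum(!is_a)
  x1 <- mat[, is_a, drop = FALSE]
  x2 <- mat[, !is_a, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  se <- sqrt(se2)
  t <- (m1 - m2) / (se + s0)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # degenerate rows: zero variance in both groups
  zero <- se2 == 0
  t[zero & m1 == m2] <- 0
  t[zero & m1 != m2] <- sign(m1 - m2)[zero & m1 != m2] * Inf
  list(log2fc = m1 - m2, t = t, df = df, zero = zero)
}

#' Two-group differential enrichment test
#'
#' Per-protein Welch t test of group A versus group B (log2FC = mean A -
#' mean B) with two-sided p-values, plus a permutation FDR: group labels
#' are permuted `n_permutations` times (unrestricted permutations, seeded)
#' and for each observed |t| threshold the q-value is the mean permutation
#' count of statistics at or above the threshold divided by the observed
#' count, capped at 1 and monotonized over the sorted statistics. An
#' optional `s0` is added to the standard error as a variance stabilizer.
#'
#' Degenerate rows (zero variance in both groups) get `p = 1` when the
#' group means are equal and `p = 0` otherwise.
#'
#' @param x An imputed `intensity_matrix` with exactly two groups of at
#'   least two samples each.
#' @param group_a Group treated as A (log2FC > 0 means higher in A);
#'   defaults to the first group level.
#' @param n_permutations Number of label permutations.
#' @param seed RNG seed for the permutations.
#' @param s0 Variance stabilizer added to the standard error.
#' @return Data frame of class `de_result`: `protein`, `log2fc`, `t`, `p`,
#'   `q`.
#' @export
differential_test <- function(x, group_a = NULL, n_permutations = 250L,
                              seed = 1L, s0 = 0) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (anyNA(x$mat)) stopf("matrix contains missing values; impute first")
  glev <- unique(unname(x$groups))
  if (length(glev) != 2L) stopf("exactly two groups required, found %d",
                                length(glev))
  if (is.null(group_a)) group_a <- glev[[1]]
  if (!group_a %in% glev) stopf("unknown group '%s'", group_a)
  is_a <- x$groups == group_a
  if (sum(is_a) < 2L || sum(!is_a) < 2L)
    stopf("each group needs at least 2 samples")
  obs <- welch_t(x$mat, is_a, s0)
  p <- 2 * stats::pt(abs(obs$t), df = obs$df, lower.tail = FALSE)
  p[obs$zero & obs$log2fc == 0] <- 1
  p[obs$zero & obs$log2fc != 0] <- 0
  abs_t <- abs(obs$t)

  # permutation FDR over |t|
  n <- ncol(x$mat)
  n1 <- sum(is_a)
  set.seed(seed)
  perm_abs <- matrix(0, nrow(x$mat), n_permutations)
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n)
    pa <- logical(n)
    pa[idx[seq_len(n1)]] <- TRUE
    pt_ <- welch_t(x$mat, pa, s0)
    at <- abs(pt_$t)
    at[pt_$zero & pt_$log2fc == 0] <- 0
    perm_abs[, b] <- at
  }
  sorted_perm <- sort(perm_abs)
  sorted_obs <- sort(abs_t)
  # counts of values >= threshold via binary search on the sorted vectors
  n_perm_ge <- length(sorted_perm) -
    findInterval(abs_t - 1e-12, sorted_perm)
  n_obs_ge <- length(sorted_obs) - findInterval(abs_t - 1e-12, sorted_obs)
  q_raw <- pmin(1, (n_perm_ge / n_permutations) / pmax(1, n_obs_ge))
  # monotonize: q non-increasing in |t|
  ord <- order(abs_t, decreasing = TRUE)
  q <- numeric(length(q_raw))
  q[ord] <- rev(cummin(rev(q_raw[ord])))
  out <- data.frame(protein = rownames(x$mat), log2fc = obs$log2fc,
                    t = obs$t, p = p, q = q, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Call significant enrichment
#'
#' Volcano mode (default) flags proteins with `|log2FC| > fc_threshold`
#' and `p < p_threshold`; FDR mode uses `q < q_threshold` together with
#' the fold-change threshold.
#'
#' @param result A `de_result`.
#' @param fc_threshold Absolute log2 fold-change threshold.
#' @param p_threshold Raw p-value threshold (volcano mode).
#' @param mode `"volcano"` or `"fdr"`.
#' @param q_threshold FDR threshold (fdr mode).
#' @return The result with a logical `significant` column and a
#'   `direction` column (`"up"`, `"down"`, `"ns"`); counts attached as
#'   attribute `counts`.
#' @export
call_significant <- function(result, fc_threshold = 1, p_threshold = 0.05,
                             mode = c("volcano", "fdr"),
                             q_threshold = 0.05) {
  mode <- match.arg(mode)
  sig <- if (mode == "volcano") {
    abs(result$log2fc) > fc_threshold & result$p < p_threshold
  } else {
    abs(result$log2fc) > fc_threshold & result$q < q_threshold
  }
  result$significant <- sig
  result$direction <- ifelse(!sig, "ns",
                             ifelse(result$log2fc > 0, "up", "down"))
  attr(result, "counts") <- c(up = sum(result$direction == "up"),
                              down = sum(result$direction == "down"))
  result
}
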