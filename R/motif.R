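# Short-linear-motif scanning, context extraction, context clustering and
# repeat competitor construct design.
#
# Patterns are plain amino-acid strings in which '.' matches any residue
# ("P.DL." finds both PLDLS and PFDLT). Scanning is exhaustive, so every
# occurrence — including overlapping ones — is reported deterministically.

#' Scan a proteome for a short linear motif
#'
#' @param proteome Data frame of sequence records ([read_fasta()]).
#' @param pattern Motif pattern over the 20 amino acids plus `'.'`
#'   (wildcard); length >= 3.
#' @param flank Context flank length in residues (see [extract_context()]).
#' @return Data frame of hits ordered by (`protein_id`, `start`): columns
#'   `protein_id`, `start` (1-based), `matched`, `context`.
#' @examples
#' prot <- data.frame(id = "p", description = "", sequence = "AAPLDLSAA")
#' scan_motif(prot, "PLDLS")
#' @export
scan_motif <- function(proteome, pattern, flank = 15L) {
  check_pattern(pattern)
  stopifnot(is.data.frame(proteome))
  ord <- order(proteome$id)
  rows <- list()
  rx <- sprintf("(?=(%s))", pattern)
  for (i in ord) {
    seq <- proteome$sequence[[i]]
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (m[[1]] == -1L) next
    for (start in as.integer(m)) {
      matched <- substr(seq, start, start + nchar(pattern) - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = proteome$id[[i]], start = start, matched = matched,
        context = extract_context(proteome[i, , drop = FALSE],
                                  start, nchar(pattern), flank),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(), start = integer(),
                      matched = character(), context = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @noRd
check_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (nchar(pattern) < 3L) stopf("motif pattern must have length >= 3")
  ch <- strsplit(pattern, "")[[1]]
  bad <- setdiff(ch, c(AA1, "."))
  if (length(bad))
    stopf("invalid pattern character(s): %s", paste(bad, collapse = ", "))
  invisible(pattern)
}

#' Extract the anchored flanking context of a motif occurrence
#'
#' Returns a fixed-length window `flank + motif + flank`; positions beyond
#' the protein termini are padded with `'-'`, so the motif always occupies
#' the same central slice of the window.
#'
#' @param record One-row data frame of sequence records, or a sequence
#'   string.
#' @param start 1-based motif start in the protein.
#' @param motif_len Motif length.
#' @param flank Flank length on each side (residues).
#' @return Character scalar of length `motif_len + 2 * flank`.
#' @export
extract_context <- function(record, start, motif_len, flank = 15L) {
  seq <- if (is.data.frame(record)) record$sequence[[1]] else record
  n <- nchar(seq)
  lo <- start - flank
  hi <- start + motif_len - 1L + flank
  left_pad <- strrep("-", max(0L, 1L - lo))
  right_pad <- strrep("-", max(0L, hi - n))
  paste0(left_pad, substr(seq, max(1L, lo), min(n, hi)), right_pad)
}

# Amino-acid classes used by the class-based context similarity. The
# grouping follows physicochemical character (small/turn-like, cysteine,
# acid/amide, basic, aliphatic, aromatic); it is configuration, not a fixed
# truth, and callers may pass their own partition.
DEFAULT_AA_CLASSES <- list(small = c("A", "G", "P", "S", "T"),
                           cys = "C",
                           acid_amide = c("D", "E", "N", "Q"),
                           basic = c("H", "K", "R"),
                           aliphatic = c("I", "L", "M", "V"),
                           aromatic = c("F", "W", "Y"))

#' Distance between two motif context windows
#'
#' Position-wise similarity averaged over columns where at least one side
#' is a residue (gap-vs-gap columns are excluded; gap-vs-residue scores 0),
#' mapped to a distance by `sqrt(1 - s)`. The `identity` scheme scores 1
#' for equal residues; `fitch_class` additionally grants `class_credit` for
#' residues of the same physicochemical class.
#'
#' @param a,b Equal-length context window strings.
#' @param scheme `"fitch_class"` (default) or `"identity"`.
#' @param classes List of character vectors partitioning the amino acids.
#' @param class_credit Similarity credit for same-class, non-identical
#'   residues.
#' @return Distance in `[0, 1]`.
#' @export
context_distance <- function(a, b, scheme = c("fitch_class", "identity"),
                             classes = DEFAULT_AA_CLASSES,
                             class_credit = 0.5) {
  scheme <- match.arg(scheme)
  if (nchar(a) != nchar(b))
    stopf("context windows have unequal lengths (%d vs %d)",
          nchar(a), nchar(b))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- !(ca == "-" & cb == "-")
  ca <- ca[keep]
  cb <- cb[keep]
  if (length(ca) == 0L) return(0)
  s <- numeric(length(ca))
  s[ca == cb & ca != "-"] <- 1
  if (scheme == "fitch_class") {
    cls <- class_lookup(classes)
    same_class <- !is.na(cls[ca]) & !is.na(cls[cb]) & cls[ca] == cls[cb] &
      ca != cb
    s[same_class] <- class_credit
  }
  gap <- ca == "-" | cb == "-"
  s[gap] <- 0
  sqrt(max(0, 1 - mean(s)))
}

#' @noRd
class_lookup <- function(classes) {
  out <- rep(names(classes), lengths(classes))
  stats::setNames(out, unlist(classes, use.names = FALSE))
}

#' Pairwise distance matrix over motif context windows
#'
#' @param contexts Character vector of equal-length context windows.
#' @param labels Row/column labels (defaults to names or indices).
#' @param ... Passed to [context_distance()].
#' @return A symmetric numeric matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
context_distance_matrix <- function(contexts, labels = NULL, ...) {
  n <- length(contexts)
  if (is.null(labels)) {
    labels <- if (!is.null(names(contexts))) names(contexts)
              else as.character(seq_len(n))
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        m[i, j] <- m[j, i] <- context_distance(contexts[[i]],
                                               contexts[[j]], ...)
      }
    }
  }
  m
}

#' Hierarchical clustering of motif contexts
#'
#' Agglomerative clustering (via [stats::hclust()]) of a context distance
#' matrix; the result is returned as an [ape::phylo] tree whose leaf set
#' equals the matrix labels and which serializes to Newick with
#' [write_newick()].
#'
#' @param dmat Symmetric distance matrix (e.g.
#'   [context_distance_matrix()]).
#' @param linkage `"complete"` (default) or `"average"`.
#' @return An [ape::phylo] tree.
#' @export
cluster_contexts <- function(dmat, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(dmat))
  if (nrow(dmat) < 2L) stopf("clustering needs at least 2 contexts")
  if (max(abs(dmat - t(dmat))) > 1e-12) stopf("distance matrix asymmetric")
  hc <- stats::hclust(stats::as.dist(dmat), method = linkage)
  ape::as.phylo(hc)
}

#' Root bipartition of a context tree
#'
#' The two-group split at the root — the partition compared against
#' planted family labels in recovery tests.
#'
#' @param tree An [ape::phylo] tree (or an `hclust`).
#' @return Named integer vector of group labels (1/2) per leaf.
#' @export
root_bipartition <- function(tree) {
  if (inherits(tree, "phylo")) {
    root <- ape::Ntip(tree) + 1L
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    grp <- stats::setNames(integer(ape::Ntip(tree)), tree$tip.label)
    for (k in seq_along(kids)) {
      tips <- if (kids[[k]] <= ape::Ntip(tree)) kids[[k]] else
        ape::extract.clade(tree, kids[[k]])$tip.label
      if (is.numeric(tips)) tips <- tree$tip.label[tips]
      grp[tips] <- k
    }
    return(grp)
  }
  stats::cutree(tree, k = 2L)
}

#' Replace motif occurrences in a sequence
#'
#' Substitutes every occurrence of a motif by a same-length replacement
#' (e.g. the inactivating PLDLS to PLASS or PFDLT to PFAST mutations),
#' leaving flanking sequence untouched.
#'
#' @param sequence Sequence or context-window string.
#' @param substitution_map Named character vector, `c(motif = replacement)`;
#'   each replacement must have the motif's length.
#' @return The mutated sequence.
#' @examples
#' mutate_motif("AAPLDLSAA", c(PLDLS = "PLASS"))
#' @export
mutate_motif <- function(sequence, substitution_map) {
  stopifnot(is.character(substitution_map), !is.null(names(substitution_map)))
  out <- sequence
  for (motif in names(substitution_map)) {
    repl <- substitution_map[[motif]]
    if (nchar(repl) != nchar(motif))
      stopf("replacement '%s' does not match motif '%s' length", repl, motif)
    out <- gsub(motif, repl, out, fixed = TRUE)
  }
  out
}

#' Assemble a repeat competitor construct
#'
#' Concatenates gap-free motif context windows (optionally motif-mutated to
#' produce the inert control), a linker between repeats, and a C-terminal
#' nuclear localization signal. The motif copy count is obtained by
#' rescanning the assembled product, so a mutated control reports 0 copies.
#'
#' @param windows Character vector of context windows, in repeat order
#'   (e.g. two human and two mouse PLDLS +/-15 aa windows).
#' @param nls Nuclear localization signal appended at the C terminus.
#' @param linker Optional linker between repeats.
#' @param motif Motif pattern counted in the product.
#' @param mutate Optional substitution map applied to every window before
#'   assembly (see [mutate_motif()]).
#' @return Object of class `competitor_construct`: list with `sequence`,
#'   `windows`, `linker`, `nls`, `motif`, `n_copies`.
#' @export
build_competitor <- function(windows, nls, linker = "", motif = "PLDLS",
                             mutate = NULL) {
  stopifnot(is.character(windows), length(windows) >= 1L)
  if (any(grepl("-", windows, fixed = TRUE)))
    stopf("windows contain gap characters; strip terminal gaps first")
  if (!is.null(mutate)) windows <- mutate_motif(windows, mutate)
  sequence <- paste0(paste(windows, collapse = linker), nls)
  prot <- data.frame(id = "construct", description = "",
                     sequence = sequence, stringsAsFactors = FALSE)
  n_copies <- nrow(scan_motif(prot, motif))
  structure(list(sequence = sequence, windows = windows, linker = linker,
                 nls = nls, motif = motif, n_copies = n_copies),
            class = "competitor_construct")
}

#' @export
print.competitor_construct <- function(x, ...) {
  cat(sprintf("competitor_construct: %d aa, %d x %s, %d repeat(s)\n",
              nchar(x$sequence), x$n_copies, x$motif, length(x$windows)))
  invisible(x)
}
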