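# Fixture builders shared across test files. Everything is constructed in
# code; no binary fixtures.

# a minimal atom row
atom_row <- function(chain, resno, x, y, z, element = "C", atom = "CA",
                     resname = "ALA") {
  data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
             element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# analytic exposed area of sphere 1 (radius R1) partially buried by
# sphere 2 (radius R2) at centre distance d: full sphere minus the buried
# spherical cap
two_sphere_exposed <- function(R1, R2, d) {
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)
}

# naive sliding-window motif scan used as the oracle for scan_motif
naive_scan <- function(proteome, pattern) {
  pl <- nchar(pattern)
  pch <- strsplit(pattern, "")[[1]]
  out <- list()
  for (i in order(proteome$id)) {
    s <- strsplit(proteome$sequence[[i]], "")[[1]]
    if (length(s) < pl) next
    for (start in seq_len(length(s) - pl + 1L)) {
      win <- s[start:(start + pl - 1L)]
      if (all(pch == "." | pch == win)) {
        out[[length(out) + 1L]] <- data.frame(
          protein_id = proteome$id[[i]], start = start,
          matched = paste(win, collapse = ""), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(protein_id = character(),
                                      start = integer(),
                                      matched = character()))
  do.call(rbind, out)
}

# per-base brute-force window counting oracle for count_windows
brute_count <- function(track_df, win_start0, win_end0) {
  # track_df: chrom-free data frame with 0-based half-open start/end/value
  total <- 0
  for (pos in seq.int(win_start0, win_end0 - 1L)) {
    row <- which(track_df$start <= pos & pos < track_df$end)
    if (length(row)) total <- total + track_df$value[[row]]
  }
  total
}

# gap-free 35-aa context window with a central PLDLS
pldls_window <- function(left = NULL, right = NULL) {
  if (is.null(left)) left <- strrep("AEKVGTRSDNQHMWY", 1)
  if (is.null(right)) right <- strrep("TSGKVAERDNQHMWY", 1)
  paste0(left, "PLDLS", right)
}

# map a bipartition (named vector of 2 labels) onto reference family
# labels; TRUE when the split matches exactly up to label swap
bipartition_matches <- function(split, families) {
  stopifnot(setequal(names(split), names(families)))
  fam <- families[names(split)]
  a <- all(split[fam == unique(fam)[1]] == split[fam == unique(fam)[1]][1]) &&
    all(split[fam == unique(fam)[2]] == split[fam == unique(fam)[2]][1]) &&
    split[fam == unique(fam)[1]][1] != split[fam == unique(fam)[2]][1]
  a
}
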