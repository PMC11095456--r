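test_that("motif scanning reports every occurrence in order", {
  p <- data.frame(id = "a", description = "", sequence = "AAPLDLSAA")
  h <- scan_motif(p, "PLDLS")
  expect_equal(h$start, 3L)
  expect_equal(h$matched, "PLDLS")

  p2 <- data.frame(id = "b", description = "", sequence = "MAPFDLTKKPLDLSW")
  h2 <- scan_motif(p2, "P.DL.")
  expect_equal(h2$start, c(3L, 10L))
  expect_equal(h2$matched, c("PFDLT", "PLDLS"))

  # overlapping occurrences are all reported
  p3 <- data.frame(id = "c", description = "", sequence = "AAAAAA")
  expect_equal(scan_motif(p3, "AAA")$start, 1:4)

  expect_error(scan_motif(p, "PL*LS"), "invalid pattern")
  expect_error(scan_motif(p, "PL"), "length >= 3")
})

test_that("a PXDLX-type wildcard finds both docking motifs in a
          two-motif zinc-finger-like sequence", {
  # synthetic fragment carrying one PFDLT and one PLDLS site, emulating
  # the two PXDLX motifs of a CTBP-binding transcription factor
  seqs <- paste0(strrep("GKEVHT", 10), "PFDLT", strrep("ASRNDQ", 10),
                 "PLDLS", strrep("WYCMIV", 10))
  p <- data.frame(id = "tf", description = "synthetic", sequence = seqs)
  h <- scan_motif(p, "P.DL.")
  expect_equal(nrow(h), 2L)
  expect_equal(h$matched, c("PFDLT", "PLDLS"))
  # exact pattern equals the wildcard pattern restricted to that motif
  expect_equal(scan_motif(p, "PLDLS")$start,
               h$start[h$matched == "PLDLS"])
})

test_that("scan_motif equals the naive sliding-window oracle", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    prot <- data.frame(
      id = sprintf("p%02d", seq_len(n)), description = "",
      sequence = vapply(seq_len(n), function(i)
        paste(sample(c("P", "L", "D", "S", "A", "T", "F"), sample(20:60, 1),
                     replace = TRUE), collapse = ""), character(1)))
    pattern <- sample(c("PLDLS", "P.DL.", "PLD", "L.S"), 1)
    got <- scan_motif(prot, pattern)
    oracle <- naive_scan(prot, pattern)
    expect_equal(got[, c("protein_id", "start", "matched")], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("scan recovers planted motifs with perfect recall/precision", {
  g <- gen_proteome(n_proteins = 120L, n_planted = 24L, seed = 7L)
  hits <- scan_motif(g$proteome, g$truth$motif)
  key <- function(df) paste(df$protein_id, df$start)
  expect_setequal(key(hits), key(g$truth$hits))
})

test_that("context windows are anchored and gap-padded at termini", {
  p <- data.frame(id = "x", description = "",
                  sequence = paste0("PLDLS", strrep("A", 40)))
  h <- scan_motif(p, "PLDLS", flank = 15L)
  expect_equal(nchar(h$context), 35L)
  expect_equal(substr(h$context, 1, 15), strrep("-", 15))
  # interior motif: no gaps
  p2 <- data.frame(id = "y", description = "",
                   sequence = paste0(strrep("A", 20), "PLDLS",
                                     strrep("C", 20)))
  h2 <- scan_motif(p2, "PLDLS")
  expect_false(grepl("-", h2$context))
  expect_equal(nchar(h2$context), 35L)
  # C-terminal motif: trailing gaps
  p3 <- data.frame(id = "z", description = "",
                   sequence = paste0(strrep("A", 40), "PLDLS"))
  h3 <- scan_motif(p3, "PLDLS")
  expect_equal(substr(h3$context, 21, 35), strrep("-", 15))
  # stripping gaps reproduces the protein subsequence
  expect_equal(gsub("-", "", h$context), substr(p$sequence, 1, 20))
})

test_that("context distance is a bounded semimetric with exact extremes", {
  w1 <- pldls_window()
  expect_equal(context_distance(w1, w1), 0)
  # no identical and no same-class positions anywhere
  a <- strrep("D", 10)
  b <- strrep("K", 10)
  expect_equal(context_distance(a, b), 1)
  expect_error(context_distance("AAA", "AAAA"), "unequal")

  set.seed(5)
  for (rep in 1:25) {
    x <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-"),
                      20, replace = TRUE), collapse = "")
    y <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-"),
                      20, replace = TRUE), collapse = "")
    for (scheme in c("identity", "fitch_class")) {
      dxy <- context_distance(x, y, scheme = scheme)
      dyx <- context_distance(y, x, scheme = scheme)
      expect_equal(dxy, dyx)
      expect_gte(dxy, 0)
      expect_lte(dxy, 1)
      expect_equal(context_distance(x, x, scheme = scheme), 0)
    }
  }
})

test_that("identity-scheme distance matches the seqinr similarity oracle", {
  skip_if_not_installed("seqinr")
  set.seed(13)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    x <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    y <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    al <- structure(list(nb = 2, nam = c("a", "b"),
                         seq = tolower(c(x, y)), com = NA),
                    class = "alignment")
    oracle <- as.numeric(seqinr::dist.alignment(al, matrix = "identity"))
    expect_equal(context_distance(x, y, scheme = "identity"), oracle,
                 tolerance = 1e-9)
  }
})

test_that("clustering merges the closest pair first and recovers planted
          families", {
  d3 <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.9,
                 0.9, 0.9, 0), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- cluster_contexts(d3)
  # a and b must be sisters
  bp <- root_bipartition(tree)
  expect_equal(bp[["a"]], bp[["b"]])
  expect_false(bp[["a"]] == bp[["c"]])

  d2 <- matrix(c(0, 0.3, 0.3, 0), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- cluster_contexts(d2)
  # single merge at the pairwise distance: cophenetic a-b distance 0.3
  expect_equal(ape::cophenetic.phylo(t2)["a", "b"], 0.3, tolerance = 1e-9)
  expect_error(cluster_contexts(d2[1, 1, drop = FALSE]), "at least 2")

  g <- gen_proteome(n_proteins = 80L, n_planted = 16L, families = 2L,
                    mutation_rate = 0.05, seed = 7L)
  hits <- scan_motif(g$proteome, g$truth$motif)
  dm <- context_distance_matrix(hits$context, hits$protein_id)
  split <- root_bipartition(cluster_contexts(dm))
  fams <- stats::setNames(g$truth$hits$family, g$truth$hits$protein_id)
  expect_true(bipartition_matches(split, fams))
  # zero mutation rate: within-family distances vanish
  g0 <- gen_proteome(n_proteins = 40L, n_planted = 8L,
                     mutation_rate = 0, seed = 3L)
  h0 <- scan_motif(g0$proteome, g0$truth$motif)
  dm0 <- context_distance_matrix(h0$context, h0$protein_id)
  fam0 <- stats::setNames(g0$truth$hits$family, g0$truth$hits$protein_id)
  same <- outer(fam0[rownames(dm0)], fam0[colnames(dm0)], "==")
  expect_true(all(dm0[same] == 0))
})

test_that("motif mutation replaces every occurrence and nothing else", {
  expect_equal(mutate_motif("AAPLDLSAA", c(PLDLS = "PLASS")), "AAPLASSAA")
  expect_equal(mutate_motif("AAPFDLTAA", c(PFDLT = "PFAST")), "AAPFASTAA")
  expect_equal(mutate_motif("AAACDEF", c(PLDLS = "PLASS")), "AAACDEF")
  expect_equal(mutate_motif("PLDLSXXPLDLS", c(PLDLS = "PLASS")),
               "PLASSXXPLASS")
  expect_error(mutate_motif("AA", c(PLDLS = "PLAS")), "length")
})

test_that("competitor construct assembles repeats, NLS and copy count", {
  win <- pldls_window()
  expect_equal(nchar(win), 35L)
  cc <- build_competitor(rep(win, 4L), nls = "PKKKRKV")
  expect_equal(nchar(cc$sequence), 147L)
  expect_equal(cc$n_copies, 4L)

  ctrl <- build_competitor(rep(win, 4L), nls = "PKKKRKV",
                           mutate = c(PLDLS = "PLASS"))
  expect_equal(ctrl$n_copies, 0L)
  # the inert control differs at exactly 2 positions per repeat
  diff <- sum(strsplit(cc$sequence, "")[[1]] !=
                strsplit(ctrl$sequence, "")[[1]])
  expect_equal(diff, 8L)

  # mixed-species repeat composition: two "human" and two "mouse" windows
  win_m <- pldls_window(left = strrep("GEKVATRSDNQHMWY", 1))
  cc2 <- build_competitor(c(win, win, win_m, win_m), nls = "PKKKRKV")
  expect_equal(cc2$n_copies, 4L)
  expect_equal(cc2$windows, c(win, win, win_m, win_m))

  expect_error(build_competitor(c(win, "AA-AA"), nls = "PKKKRKV"),
               "gap")
})
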