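test_that("isolated and well-separated atoms get full-sphere SASA", {
  a <- atom_row("A", 1, 0, 0, 0)
  s <- compute_sasa(a)
  expect_equal(s$atom_sasa, 4 * pi * 3.1^2, tolerance = 1e-12)
  far <- rbind(a, atom_row("A", 2, 100, 0, 0))
  s2 <- compute_sasa(far)
  expect_equal(s2$atom_sasa, rep(4 * pi * 3.1^2, 2), tolerance = 1e-12)
  expect_error(compute_sasa(a[0, ]), "zero atoms")
})

test_that("two-sphere SASA matches the analytic spherical-cap area", {
  for (d in c(1.5, 2.5, 3.5, 4.5, 5.5)) {
    m <- rbind(atom_row("A", 1, 0, 0, 0, element = "C"),
               atom_row("A", 2, d, 0, 0, element = "O"))
    s <- compute_sasa(m, n_points = 960L)
    R1 <- 1.70 + 1.4
    R2 <- 1.52 + 1.4
    expect_lt(abs(s$atom_sasa[[1]] - two_sphere_exposed(R1, R2, d)) /
                two_sphere_exposed(R1, R2, d), 0.02)
    expect_lt(abs(s$atom_sasa[[2]] - two_sphere_exposed(R2, R1, d)) /
                two_sphere_exposed(R2, R1, d), 0.02)
  }
})

test_that("SASA upper bound and burial non-negativity hold", {
  g <- gen_complex_ensemble(n_models = 1L, n_res_a = 8L, n_res_b = 8L,
                            n_contact_pairs = 4L, seed = 3L)
  model <- g$ensemble[[1]]
  s <- compute_sasa(model)
  expect_true(all(s$atom_sasa >= 0))
  expect_true(all(s$atom_sasa <=
                    4 * pi * (vdw_max <- 1.8 + 1.4)^2 + 1e-9))
  # in-complex per-residue SASA never exceeds the isolated-chain value
  for (ch in c("A", "B")) {
    iso <- compute_sasa(model[model$chain == ch, ])$residue_sasa
    cx <- s$residue_sasa[s$residue_sasa$chain == ch, ]
    expect_true(all(cx$sasa <= iso$sasa + 1e-6))
  }
})

test_that("interface calls flag planted contacts and nothing else", {
  g <- gen_complex_ensemble(n_models = 1L, jitter_sigma = 0, seed = 7L)
  model <- g$ensemble[[1]]
  for (method in c("contact", "buried_sasa")) {
    ir <- call_interface(model, "A", "B", method = method)
    for (ch in c("A", "B")) {
      got <- sort(ir$residues$resno[ir$residues$interfacial &
                                      ir$residues$chain == ch])
      expect_equal(got, g$truth$planted_a, info = paste(method, ch))
    }
  }
  expect_error(call_interface(model, "A", "Z"), "chain 'Z'")
  expect_error(call_interface(model[model$chain == "A", ], "A", "B"),
               "single chain")
})

test_that("chains separated by 100 A have empty interfaces", {
  a <- atom_row("A", 1:3, c(0, 3.8, 7.6), 0, 0)
  b <- atom_row("B", 1:3, c(0, 3.8, 7.6), 100, 0)
  ir <- call_interface(rbind(a, b), "A", "B", method = "contact")
  expect_false(any(ir$residues$interfacial))
  ir2 <- call_interface(rbind(a, b), "A", "B", method = "buried_sasa")
  expect_false(any(ir2$residues$interfacial))
})

test_that("buried_sasa calls equal an independent per-residue dSASA scan", {
  g <- gen_complex_ensemble(n_models = 1L, n_res_a = 10L, n_res_b = 10L,
                            n_contact_pairs = 4L, seed = 5L)
  model <- g$ensemble[[1]]
  ir <- call_interface(model, "A", "B", method = "buried_sasa")
  for (ch in c("A", "B")) {
    iso <- compute_sasa(model[model$chain == ch, ])$residue_sasa
    cx <- compute_sasa(model)$residue_sasa
    cx <- cx[cx$chain == ch, ]
    dsasa <- iso$sasa - cx$sasa[match(iso$resno, cx$resno)]
    oracle <- iso$resno[dsasa > 0.1]
    got <- ir$residues$resno[ir$residues$interfacial &
                               ir$residues$chain == ch]
    expect_equal(sort(got), sort(oracle))
  }
})

test_that("contact calling is monotone in the cutoff", {
  g <- gen_complex_ensemble(n_models = 1L, jitter_sigma = 0, seed = 2L)
  model <- g$ensemble[[1]]
  none <- call_interface(model, "A", "B", method = "contact",
                         contact_cutoff = 1e-6)
  expect_false(any(none$residues$interfacial))
  all_res <- call_interface(model, "A", "B", method = "contact",
                            contact_cutoff = 1e6)
  expect_true(all(all_res$residues$interfacial))
})

test_that("ensemble frequency counts models and is order-invariant", {
  g <- gen_complex_ensemble(n_models = 4L, jitter_sigma = 0, seed = 9L)
  freq <- ensemble_interface_frequency(g$ensemble, "A", "B",
                                       method = "contact")
  planted <- freq$resno %in% g$truth$planted_a
  expect_true(all(freq$frequency[planted] == 1))
  expect_true(all(freq$frequency[!planted] == 0))
  expect_true(all(freq$n_models == 4L))

  shuffled <- structure(g$ensemble[c(3, 1, 4, 2)],
                        class = "structure_ensemble")
  freq2 <- ensemble_interface_frequency(shuffled, "A", "B",
                                        method = "contact")
  expect_equal(freq2$frequency, freq$frequency)

  # fractional frequency: make one model non-interfacial by translation
  ens <- g$ensemble
  ens[[1]]$y[ens[[1]]$chain == "B"] <- ens[[1]]$y[ens[[1]]$chain == "B"] + 50
  freq3 <- ensemble_interface_frequency(
    structure(ens, class = "structure_ensemble"), "A", "B",
    method = "contact")
  expect_equal(unique(freq3$frequency[planted]), 3 / 4)
})

test_that("inconsistent residue numbering across models is rejected", {
  g <- gen_complex_ensemble(n_models = 2L, n_res_a = 5L, n_res_b = 5L,
                            n_contact_pairs = 3L, seed = 1L)
  ens <- g$ensemble
  ens[[2]]$resno[ens[[2]]$chain == "A"] <-
    ens[[2]]$resno[ens[[2]]$chain == "A"] + 100L
  expect_error(ensemble_interface_frequency(
    structure(ens, class = "structure_ensemble"), "A", "B",
    method = "contact"), "inconsistent")
})

test_that("consensus segments equal brute-force run enumeration", {
  mk_freq <- function(fr) {
    data.frame(chain = "A", resno = seq_along(fr),
               resname = "ALA", count = round(fr * 10), n_models = 10,
               frequency = fr)
  }
  expect_equal(nrow(consensus_segments(mk_freq(rep(0, 20)), "A")), 0L)
  one <- consensus_segments(mk_freq(c(rep(0, 5), rep(1, 5), rep(0, 5))),
                            "A")
  expect_equal(one$start_res, 6L)
  expect_equal(one$end_res, 10L)
  expect_equal(one$length, 5L)

  set.seed(31)
  for (rep in 1:20) {
    fr <- round(stats::runif(30), 2)
    segs <- consensus_segments(mk_freq(fr), "A", threshold = 0.5,
                               min_run = 3L)
    # brute force: enumerate all maximal runs
    hot <- fr >= 0.5
    runs <- rle(hot)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & runs$lengths >= 3L
    expect_equal(segs$start_res, starts[keep])
    expect_equal(segs$end_res, ends[keep])
  }
})

test_that("hydrogen bonds follow the distance and angle criteria", {
  # donor N with antecedent C at 165 deg from the acceptor direction; the
  # acceptor O gets its own antecedent oriented so the reverse O->N
  # direction fails the angle criterion
  ante <- c(cos(165 * pi / 180), sin(165 * pi / 180), 0) * 1.5
  ante_b <- c(2.9, 0, 0) + c(-cos(20 * pi / 180), sin(20 * pi / 180), 0) * 1.4
  m <- rbind(atom_row("A", 1, 0, 0, 0, element = "N", atom = "N"),
             atom_row("A", 1, ante[1], ante[2], ante[3], element = "C",
                      atom = "C"),
             atom_row("B", 1, 2.9, 0, 0, element = "O", atom = "O"),
             atom_row("B", 1, ante_b[1], ante_b[2], ante_b[3],
                      element = "C", atom = "C"))
  hb <- detect_hbonds(m, "A", "B")
  hb <- hb[hb$donor_atom == "N" & hb$acceptor_atom == "O", ]
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 165, tolerance = 1e-6)

  # too far
  m_far <- m
  m_far$x[[3]] <- 4.0
  expect_equal(nrow(detect_hbonds(m_far, "A", "B")), 0L)

  # angle below the cutoff
  ante2 <- c(cos(80 * pi / 180), sin(80 * pi / 180), 0) * 1.5
  m_bad <- m
  m_bad[2, c("x", "y", "z")] <- as.list(ante2)
  expect_equal(nrow(detect_hbonds(m_bad, "A", "B")), 0L)
})

test_that("hbond detection equals an exhaustive cross-chain N/O scan", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 12L
    m <- data.frame(chain = rep(c("A", "B"), each = n),
                    resno = rep(seq_len(n), 2L),
                    resname = "ALA",
                    atom = sample(c("N", "O", "C"), 2L * n, replace = TRUE),
                    stringsAsFactors = FALSE)
    m$element <- substr(m$atom, 1, 1)
    m$x <- stats::runif(2L * n, 0, 12)
    m$y <- stats::runif(2L * n, 0, 12)
    m$z <- stats::runif(2L * n, 0, 12)
    hb <- detect_hbonds(m, "A", "B", d_max = 3.5, angle_min = 120)
    # oracle: nested loops over ordered donor/acceptor pairs
    found <- 0L
    xyz <- as.matrix(m[, c("x", "y", "z")])
    for (d in which(m$element %in% c("N", "O"))) {
      for (a in which(m$element %in% c("N", "O") & m$chain != m$chain[d])) {
        dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
        if (dist > 3.5) next
        same <- which(m$chain == m$chain[d] & m$resno == m$resno[d] &
                        m$element != "H" & seq_len(nrow(m)) != d)
        ds <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[d, ])^2))
        cand <- same[ds < 2.0]
        ok <- TRUE
        if (length(cand)) {
          ante <- cand[[which.min(ds[ds < 2.0])]]
          v1 <- xyz[ante, ] - xyz[d, ]
          v2 <- xyz[a, ] - xyz[d, ]
          ang <- acos(min(1, max(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          ok <- ang >= 120
        }
        if (ok) found <- found + 1L
      }
    }
    expect_equal(nrow(hb), found)
  }
})
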