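# Seeded synthetic-data generators with planted ground truth.
#
# Each generator is a pure function of its parameters and seed: rerunning
# with the same arguments reproduces the data byte for byte. Generators
# return in-memory objects plus a `truth` list sufficient to score any
# downstream stage; pass `dir` to also write the standard file formats
# (PDB/FASTA/TSV/BED/bedGraph) together with `truth.json`.

#' @noRd
write_truth <- function(truth, dir, stage) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @noRd
random_aa <- function(n) paste(sample(AA1, n, replace = TRUE), collapse = "")

#' Simulate a jittered structure ensemble with a planted interface
#'
#' Two idealized chains (one C-alpha plus one pseudo-side-chain atom per
#' residue, 3.8 A spacing) are posed 20 A apart; a contiguous run of
#' `n_contact_pairs` residues is planted as the interface by bending the
#' side-chain atoms of both chains toward each other to a 3.5 A cross-chain
#' distance — emulating a docked short-linear-motif segment. Each model of
#' the ensemble receives i.i.d. Gaussian coordinate jitter.
#'
#' @param n_models Ensemble size (e.g. 25 models per heterodimer
#'   prediction).
#' @param n_res_a,n_res_b Residues per chain.
#' @param n_contact_pairs Length of the planted contiguous interface run.
#' @param jitter_sigma Per-coordinate jitter SD in Angstrom.
#' @param seed RNG seed.
#' @param dir Optional output directory (`ensemble.pdb`, `truth.json`).
#' @return List with `ensemble` (a `structure_ensemble`) and `truth`
#'   (planted residue numbers per chain, parameters, seed).
#' @export
gen_complex_ensemble <- function(n_models = 25L, n_res_a = 30L,
                                 n_res_b = 30L, n_contact_pairs = 5L,
                                 jitter_sigma = 0.3, seed = 1L,
                                 dir = NULL) {
  stopifnot(n_models >= 1L, n_res_a >= 1L, n_res_b >= 1L,
            n_contact_pairs >= 1L, jitter_sigma >= 0)
  n_shared <- min(n_res_a, n_res_b)
  if (n_contact_pairs > n_shared)
    stopf("cannot plant %d contact pairs on chains of %d shared positions",
          n_contact_pairs, n_shared)
  set.seed(seed)
  run_start <- sample.int(n_shared - n_contact_pairs + 1L, 1L)
  planted <- seq.int(run_start, run_start + n_contact_pairs - 1L)
  resnames_a <- sample(AA3, n_res_a, replace = TRUE)
  resnames_b <- sample(AA3, n_res_b, replace = TRUE)
  base <- function(chain, n, resnames, y_ca, y_cb, y_cb_planted) {
    cb_y <- rep(y_cb, n)
    cb_y[planted[planted <= n]] <- y_cb_planted
    data.frame(chain = chain, resno = rep(seq_len(n), each = 2L),
               resname = rep(unname(resnames), each = 2L),
               atom = rep(c("CA", "CB"), n),
               element = "C",
               x = rep(3.8 * (seq_len(n) - 1L), each = 2L),
               y = as.vector(rbind(rep(y_ca, n), cb_y)),
               z = 0, stringsAsFactors = FALSE)
  }
  # planted side chains meet at 3.5 A across the 20 A chain gap
  ref <- rbind(base("A", n_res_a, resnames_a, 0, -2.0, 8.25),
               base("B", n_res_b, resnames_b, 20, 22.0, 11.75))
  models <- lapply(seq_len(n_models), function(m) {
    df <- ref
    jit <- stats::rnorm(3L * nrow(df), sd = jitter_sigma)
    df$x <- df$x + jit[seq_len(nrow(df))]
    df$y <- df$y + jit[nrow(df) + seq_len(nrow(df))]
    df$z <- df$z + jit[2L * nrow(df) + seq_len(nrow(df))]
    df
  })
  ensemble <- structure(models, class = "structure_ensemble")
  truth <- list(stage = "complex_ensemble",
                planted_a = planted, planted_b = planted,
                params = list(n_models = n_models, n_res_a = n_res_a,
                              n_res_b = n_res_b,
                              n_contact_pairs = n_contact_pairs,
                              jitter_sigma = jitter_sigma),
                seed = seed)
  if (!is.null(dir)) {
    write_truth(truth, dir, "complex_ensemble")
    write_pdb_models(ensemble, file.path(dir, "ensemble.pdb"))
  }
  list(ensemble = ensemble, truth = truth)
}

#' Simulate a proteome with planted motif instances in context families
#'
#' Background sequences are i.i.d. uniform over the 20 amino acids with
#' accidental motif occurrences scrubbed out. Planted proteins carry one
#' motif copy flanked by a family-specific context template mutated per
#' site at `mutation_rate` (motif letters never mutated); insertion points
#' keep the full flank inside the protein, so planted contexts are
#' gap-free.
#'
#' @param n_proteins Total proteins.
#' @param n_planted Proteins receiving a planted motif.
#' @param families Number of context families.
#' @param mutation_rate Per-site flank mutation probability.
#' @param flank Context flank length.
#' @param motif Planted motif (exact sequence).
#' @param seed RNG seed.
#' @param dir Optional output directory (`proteome.fa`, `truth.json`).
#' @return List with `proteome` (sequence-record data frame) and `truth`
#'   (planted hits with family labels).
#' @export
gen_proteome <- function(n_proteins = 500L, n_planted = 40L, families = 2L,
                         mutation_rate = 0.05, flank = 15L,
                         motif = "PLDLS", seed = 1L, dir = NULL) {
  stopifnot(n_planted <= n_proteins, mutation_rate >= 0, mutation_rate <= 1)
  set.seed(seed)
  mlen <- nchar(motif)
  ids <- sprintf("prot%04d", seq_len(n_proteins))
  planted_idx <- sort(sample.int(n_proteins, n_planted))
  fam <- rep_len(seq_len(families), n_planted)
  templates <- replicate(families, list(left = random_aa(flank),
                                        right = random_aa(flank)),
                         simplify = FALSE)
  mutate_flank <- function(tmpl) {
    ch <- strsplit(tmpl, "")[[1]]
    hit <- stats::runif(length(ch)) < mutation_rate
    for (i in which(hit)) ch[[i]] <- sample(setdiff(AA1, ch[[i]]), 1L)
    paste(ch, collapse = "")
  }
  scrub <- function(seq, keep_start = NA) {
    # re-randomize accidental motif occurrences (planted copy preserved)
    repeat {
      pos <- as.integer(gregexpr(motif, seq, fixed = TRUE)[[1]])
      pos <- pos[pos > 0 & (is.na(keep_start) | pos != keep_start)]
      if (length(pos) == 0L) return(seq)
      substr(seq, pos[[1]], pos[[1]]) <- sample(setdiff(AA1,
        substr(seq, pos[[1]], pos[[1]])), 1L)
    }
  }
  seqs <- character(n_proteins)
  starts <- integer(n_planted)
  k <- 0L
  for (i in seq_len(n_proteins)) {
    len <- sample(200:400, 1L)
    if (i %in% planted_idx) {
      k <- k + 1L
      tmpl <- templates[[fam[[k]]]]
      pre <- sample.int(len - 2L * flank - mlen, 1L)
      post <- len - pre - 2L * flank - mlen
      s <- paste0(random_aa(pre), mutate_flank(tmpl$left), motif,
                  mutate_flank(tmpl$right), random_aa(post))
      starts[[k]] <- pre + flank + 1L
      seqs[[i]] <- scrub(s, keep_start = starts[[k]])
    } else {
      seqs[[i]] <- scrub(random_aa(len))
    }
  }
  proteome <- data.frame(id = ids, description = "", sequence = seqs,
                         stringsAsFactors = FALSE)
  truth <- list(stage = "proteome", motif = motif,
                hits = data.frame(protein_id = ids[planted_idx],
                                  start = starts, family = fam,
                                  stringsAsFactors = FALSE),
                params = list(n_proteins = n_proteins,
                              n_planted = n_planted, families = families,
                              mutation_rate = mutation_rate, flank = flank),
                seed = seed)
  if (!is.null(dir)) {
    write_truth(truth, dir, "proteome")
    write_fasta(proteome, file.path(dir, "proteome.fa"))
  }
  list(proteome = proteome, truth = truth)
}

#' Simulate a complex database with planted protein modules
#'
#' Module proteins are co-assigned to many shared complexes (including one
#' complex per module equal to the full module); background complexes draw
#' members independently from the non-module proteins. The hit list is the
#' module proteins plus background decoys.
#'
#' @param n_complexes Total complexes.
#' @param n_proteins Total proteins in the universe.
#' @param planted_modules Number of planted modules.
#' @param module_size Proteins per module.
#' @param n_decoys Background proteins added to the hit list.
#' @param seed RNG seed.
#' @param dir Optional output directory (`complexes.tsv`, `hits.txt`,
#'   `truth.json`).
#' @return List with `db` (a `complex_db`), `hits` (character vector) and
#'   `truth` (module membership, decoys).
#' @export
gen_complex_db <- function(n_complexes = 200L, n_proteins = 1000L,
                           planted_modules = 2L, module_size = 15L,
                           n_decoys = 10L, seed = 1L, dir = NULL) {
  stopifnot(planted_modules * module_size + n_decoys <= n_proteins)
  set.seed(seed)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  picked <- sample(proteins, planted_modules * module_size)
  modules <- split(picked, rep(seq_len(planted_modules), each = module_size))
  names(modules) <- sprintf("module%d", seq_len(planted_modules))
  background <- setdiff(proteins, picked)
  complexes <- list()
  for (m in seq_len(planted_modules)) {
    complexes[[sprintf("CPX_M%d_full", m)]] <- modules[[m]]
    for (r in seq_len(14L)) {
      sz <- sample(8:12, 1L)
      complexes[[sprintf("CPX_M%d_%02d", m, r)]] <- sample(modules[[m]], sz)
    }
  }
  n_bg <- n_complexes - length(complexes)
  if (n_bg < 0L) stopf("n_complexes too small for the planted modules")
  for (b in seq_len(n_bg)) {
    sz <- sample(3:10, 1L)
    complexes[[sprintf("CPX_BG_%03d", b)]] <- sample(background, sz)
  }
  db <- complex_db(complexes)
  decoys <- sort(sample(intersect(background, rownames(db$membership)),
                        n_decoys))
  hits <- c(unlist(modules, use.names = FALSE), decoys)
  truth <- list(stage = "complex_db", modules = modules, decoys = decoys,
                params = list(n_complexes = n_complexes,
                              n_proteins = n_proteins,
                              planted_modules = planted_modules,
                              module_size = module_size),
                seed = seed)
  if (!is.null(dir)) {
    write_truth(truth, dir, "complex_db")
    write_complex_db(db, file.path(dir, "complexes.tsv"))
    writeLines(hits, file.path(dir, "hits.txt"))
  }
  list(db = db, hits = hits, truth = truth)
}

#' Simulate a two-group log2 LFQ matrix with planted enrichment
#'
#' Per-protein baselines are N(20, 1) on the log2 scale; enriched proteins
#' are shifted by `effect` in group A; within-group noise is N(0,
#' sigma^2). Abundance-dependent missingness censors every value below the
#' `censor_quantile` quantile of the full matrix, emulating the
#' left-censored missingness of label-free MS.
#'
#' @param n_proteins Total proteins.
#' @param n_enriched Planted enriched proteins.
#' @param effect Log2 shift in group A.
#' @param sigma Within-group noise SD.
#' @param n_per_group Samples per group.
#' @param censor_quantile Fraction of lowest values set missing.
#' @param seed RNG seed.
#' @param dir Optional output directory (`lfq.tsv`, `samples.tsv`,
#'   `truth.json`).
#' @return List with `matrix` (an `intensity_matrix`) and `truth`
#'   (enriched protein ids).
#' @export
gen_lfq <- function(n_proteins = 2000L, n_enriched = 50L, effect = 4,
                    sigma = 0.3, n_per_group = 3L, censor_quantile = 0.1,
                    seed = 1L, dir = NULL) {
  stopifnot(n_enriched <= n_proteins, sigma > 0, n_per_group >= 2L)
  set.seed(seed)
  proteins <- sprintf("prot%05d", seq_len(n_proteins))
  enriched <- sort(sample(proteins, n_enriched))
  samples <- c(sprintf("A%d", seq_len(n_per_group)),
               sprintf("B%d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("A", "B"), each = n_per_group), samples)
  baseline <- stats::rnorm(n_proteins, 20, 1)
  mat <- baseline + matrix(stats::rnorm(n_proteins * 2L * n_per_group,
                                        sd = sigma),
                           n_proteins, 2L * n_per_group)
  mat[proteins %in% enriched, seq_len(n_per_group)] <-
    mat[proteins %in% enriched, seq_len(n_per_group)] + effect
  dimnames(mat) <- list(proteins, samples)
  if (censor_quantile > 0) {
    thr <- stats::quantile(mat, censor_quantile, names = FALSE)
    mat[mat < thr] <- NA
  }
  x <- intensity_matrix(mat, groups)
  truth <- list(stage = "lfq", enriched = enriched,
                params = list(n_proteins = n_proteins,
                              n_enriched = n_enriched, effect = effect,
                              sigma = sigma, n_per_group = n_per_group,
                              censor_quantile = censor_quantile),
                seed = seed)
  if (!is.null(dir)) {
    write_truth(truth, dir, "lfq")
    write_intensity_matrix(x, file.path(dir, "lfq.tsv"),
                           file.path(dir, "samples.tsv"))
  }
  list(matrix = x, truth = truth)
}

#' Simulate correlated ChIP coverage tracks over planted peaks
#'
#' Non-overlapping peaks on a single synthetic chromosome (`chrS`, spaced
#' ten window-widths apart); per-peak log-rates are drawn from an
#' equicorrelated Gaussian (pairwise correlation `rho`, shared-factor
#' construction) and each track's signal over a peak window is
#' Poisson(`depth` times rate), spread uniformly over the window.
#'
#' @param n_peaks Number of peaks.
#' @param tracks Number of coverage tracks.
#' @param rho Pairwise log-rate correlation in [0, 1].
#' @param depth Mean counts per unit rate (sequencing depth proxy).
#' @param flank Window flank (window width = 2 * flank).
#' @param peak_width Planted peak width in bp.
#' @param seed RNG seed.
#' @param dir Optional output directory (`peaks.bed`, `track<i>.bedgraph`,
#'   `chrom.sizes`, `truth.json`).
#' @return List with `peaks` (GRanges), `tracks` (named list of
#'   `coverage_track`), `chrom_sizes`, `truth` (per-window rates, rho).
#' @export
gen_chip <- function(n_peaks = 2000L, tracks = 2L, rho = 0.8, depth = 30,
                     flank = 1000L, peak_width = 200L, seed = 1L,
                     dir = NULL) {
  stopifnot(rho >= 0, rho <= 1, tracks >= 2L, depth > 0)
  set.seed(seed)
  spacing <- 10L * 2L * flank
  chrom_len <- (n_peaks + 1L) * spacing
  starts0 <- spacing * seq_len(n_peaks) - floor(peak_width / 2)
  peaks <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(start = starts0 + 1, width = peak_width),
    name = sprintf("peak%05d", seq_len(n_peaks)))
  f <- stats::rnorm(n_peaks)
  z <- vapply(seq_len(tracks), function(t)
    sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n_peaks),
    numeric(n_peaks))
  rates <- exp(z)
  windows <- make_windows(peaks, flank = flank)
  track_list <- list()
  for (t in seq_len(tracks)) {
    n_reads <- stats::rpois(n_peaks, depth * rates[, t])
    gr <- windows
    S4Vectors::mcols(gr) <- NULL
    gr$value <- n_reads / (2 * flank)
    gr <- gr[gr$value > 0]
    track_list[[sprintf("track%d", t)]] <- coverage_track(gr)
  }
  chrom_sizes <- c(chrS = chrom_len)
  truth <- list(stage = "chip", rho = rho, log_rates = z,
                params = list(n_peaks = n_peaks, tracks = tracks,
                              depth = depth, flank = flank,
                              peak_width = peak_width),
                seed = seed)
  if (!is.null(dir)) {
    truth_out <- truth
    truth_out$log_rates <- NULL  # bulky; rates are derivable from the seed
    write_truth(truth_out, dir, "chip")
    write_bed(peaks, file.path(dir, "peaks.bed"))
    for (t in names(track_list)) {
      write_bedgraph(track_list[[t]], file.path(dir, paste0(t, ".bedgraph")))
    }
    writeLines(sprintf("chrS\t%d", chrom_len),
               file.path(dir, "chrom.sizes"))
  }
  list(peaks = peaks, tracks = track_list, chrom_sizes = chrom_sizes,
       truth = truth)
}
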