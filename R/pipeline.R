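# Stage runner: one entry point wiring the analysis stages, with YAML
# config, a provenance manifest per run, and atomic (temp-then-rename)
# output writing. All randomness flows from the single `seed` field.

RUN_CONFIG_KEYS <- c("stage", "params", "inputs", "output_dir", "seed",
                     "log_level")

#' Build a run configuration
#'
#' @param stage One of `"simulate"`, `"interface"`, `"motif"`,
#'   `"network"`, `"ipms"`, `"chip"`.
#' @param params Named list of stage parameters (defaults of the
#'   underlying functions apply).
#' @param inputs Named list of input paths.
#' @param output_dir Output directory (created if needed).
#' @param seed Integer seed driving all stage randomness.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(stage, params = list(), inputs = list(),
                       output_dir, seed = 1L, log_level = "info") {
  cfg <- list(stage = stage, params = params, inputs = inputs,
              output_dir = output_dir, seed = as.integer(seed),
              log_level = log_level)
  validate_run_config(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys are the `run_config()` fields; unknown keys are
#' rejected before any computation.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @noRd
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(cfg$stage) || !cfg$stage %in% names(stage_registry()))
    stopf("config must name a stage among: %s",
          paste(names(stage_registry()), collapse = ", "))
  if (is.null(cfg$output_dir)) stopf("config must set output_dir")
  cfg$params <- if (is.null(cfg$params)) list() else cfg$params
  cfg$inputs <- if (is.null(cfg$inputs)) list() else cfg$inputs
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$log_level <- if (is.null(cfg$log_level)) "info" else cfg$log_level
  structure(cfg, class = "run_config")
}

#' @noRd
log_msg <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf(paste0("[%s] ", fmt), cfg$stage, ...))
}

#' @noRd
check_inputs <- function(cfg, required) {
  for (key in required) {
    paths <- cfg$inputs[[key]]
    if (is.null(paths)) stopf("stage '%s' requires input '%s'",
                              cfg$stage, key)
    for (p in paths) if (!file.exists(p)) stopf("input not found: %s", p)
  }
}

#' @noRd
write_tsv_atomic <- function(df, dir, name) {
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, file.path(dir, name))
  file.path(dir, name)
}

#' @noRd
write_manifest <- function(cfg, outputs, dir) {
  hashes <- lapply(cfg$inputs, function(paths)
    vapply(paths, function(p) unname(tools::md5sum(p)), character(1)))
  manifest <- list(stage = cfg$stage, params = cfg$params,
                   inputs = cfg$inputs, input_md5 = hashes,
                   seed = cfg$seed, outputs = basename(unlist(outputs)),
                   package = "slimcore",
                   version = as.character(utils::packageVersion("slimcore")))
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}

#' @noRd
stage_registry <- function() {
  list(simulate = stage_simulate, interface = stage_interface,
       motif = stage_motif, network = stage_network, ipms = stage_ipms,
       chip = stage_chip)
}

#' Run one pipeline stage from a configuration
#'
#' Validates the configuration and inputs, executes the stage through the
#' package's analysis functions, and writes the outputs plus a
#' `manifest.json` echoing the resolved configuration, input checksums and
#' package version. Reruns with an identical configuration and seed
#' produce byte-identical outputs.
#'
#' @param cfg A `run_config` (or path to a YAML config file).
#' @return Invisibly, a character vector of output paths.
#' @export
run_stage <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(unclass(cfg))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- stage_registry()[[cfg$stage]](cfg)
  write_manifest(cfg, outputs, cfg$output_dir)
  log_msg(cfg, "wrote %d output file(s) to %s", length(outputs),
          cfg$output_dir)
  invisible(unlist(outputs))
}

#' @noRd
stage_simulate <- function(cfg) {
  p <- cfg$params
  what <- p$what
  if (is.null(what)) stopf("simulate stage requires params$what")
  p$what <- NULL
  gen <- switch(what,
                ensemble = gen_complex_ensemble, proteome = gen_proteome,
                complexdb = gen_complex_db, lfq = gen_lfq, chip = gen_chip,
                stopf("unknown generator '%s'", what))
  do.call(gen, c(p, list(seed = cfg$seed, dir = cfg$output_dir)))
  setdiff(list.files(cfg$output_dir, full.names = TRUE),
          file.path(cfg$output_dir, "manifest.json"))
}

#' @noRd
stage_interface <- function(cfg) {
  check_inputs(cfg, "pdb")
  p <- cfg$params
  ens <- read_pdb_models(cfg$inputs$pdb)
  log_msg(cfg, "read %d model(s)", length(ens))
  args <- c(list(ens, p$chain_a %||% "A", p$chain_b %||% "B"),
            p[intersect(names(p), c("method", "area_cutoff",
                                    "contact_cutoff", "n_points"))])
  freq <- do.call(ensemble_interface_frequency, args)
  segs <- do.call(rbind, lapply(unique(freq$chain), function(ch)
    consensus_segments(freq, ch, threshold = p$threshold %||% 0.5,
                       min_run = p$min_run %||% 3L)))
  list(write_tsv_atomic(freq, cfg$output_dir, "freq.tsv"),
       write_tsv_atomic(segs, cfg$output_dir, "segments.tsv"))
}

#' @noRd
stage_motif <- function(cfg) {
  check_inputs(cfg, "fasta")
  p <- cfg$params
  proteome <- read_fasta(cfg$inputs$fasta)
  hits <- scan_motif(proteome, p$pattern %||% "PLDLS",
                     flank = p$flank %||% 15L)
  log_msg(cfg, "%d motif hit(s) in %d protein(s)", nrow(hits),
          length(unique(hits$protein_id)))
  out <- list(write_tsv_atomic(hits, cfg$output_dir, "hits.tsv"))
  if (nrow(hits) >= 2L) {
    labels <- paste(hits$protein_id, hits$start, sep = "_")
    dmat <- context_distance_matrix(hits$context, labels,
                                    scheme = p$scheme %||% "fitch_class")
    tree <- cluster_contexts(dmat, linkage = p$linkage %||% "complete")
    nwk_tmp <- tempfile(tmpdir = cfg$output_dir, fileext = ".tmp")
    writeLines(write_newick(tree), nwk_tmp)
    file.rename(nwk_tmp, file.path(cfg$output_dir, "tree.nwk"))
    out <- c(out, file.path(cfg$output_dir, "tree.nwk"))
  }
  out
}

#' @noRd
stage_network <- function(cfg) {
  check_inputs(cfg, c("db", "hits"))
  p <- cfg$params
  db <- read_complex_db(cfg$inputs$db)
  hits <- readLines(cfg$inputs$hits, warn = FALSE)
  hits <- hits[nzchar(hits)]
  enr <- complex_enrichment(hits, db)
  g <- build_cocomplex_graph(db, hits, resolution = p$resolution %||% 1,
                             seed = cfg$seed,
                             iterations = p$iterations %||% 50L)
  log_msg(cfg, "%d nodes, %d edges, %d communities", nrow(g$nodes),
          nrow(g$edges), length(unique(g$nodes$community)))
  list(write_tsv_atomic(enr, cfg$output_dir, "enrichment.tsv"),
       write_tsv_atomic(g$edges, cfg$output_dir, "edges.tsv"),
       write_tsv_atomic(g$nodes, cfg$output_dir, "nodes.tsv"))
}

#' @noRd
stage_ipms <- function(cfg) {
  check_inputs(cfg, c("matrix", "samples"))
  p <- cfg$params
  x <- read_intensity_matrix(cfg$inputs$matrix, cfg$inputs$samples)
  n_in <- nrow(x$mat)
  x <- filter_valid(x, min_valid = p$min_valid %||% 3L,
                    scope = p$scope %||% "any_group")
  log_msg(cfg, "%d of %d protein(s) pass the valid-value filter",
          nrow(x$mat), n_in)
  x <- impute_missing(x, strategy = p$impute %||% "below_min",
                      shift = p$shift %||% 0.5, value = p$value,
                      seed = cfg$seed)
  res <- differential_test(x, group_a = p$group_a,
                           n_permutations = p$perms %||% 250L,
                           seed = cfg$seed, s0 = p$s0 %||% 0)
  res <- call_significant(res, fc_threshold = p$fc %||% 1,
                          p_threshold = p$p %||% 0.05)
  list(write_tsv_atomic(res, cfg$output_dir, "de.tsv"))
}

#' @noRd
stage_chip <- function(cfg) {
  check_inputs(cfg, c("peaks", "tracks"))
  p <- cfg$params
  peaks <- read_bed(cfg$inputs$peaks)
  chrom_sizes <- NULL
  if (!is.null(cfg$inputs$chrom_sizes)) {
    cs <- utils::read.table(cfg$inputs$chrom_sizes, sep = "\t",
                            stringsAsFactors = FALSE)
    chrom_sizes <- stats::setNames(cs[[2]], cs[[1]])
  }
  windows <- make_windows(peaks, flank = p$flank %||% 1000L,
                          mode = p$mode %||% "center",
                          chrom_sizes = chrom_sizes)
  log_msg(cfg, "%d window(s), %d dropped at bounds", length(windows),
          attr(windows, "n_dropped"))
  tracks <- lapply(cfg$inputs$tracks, read_bedgraph)
  names(tracks) <- sub("\\.(bedgraph|bg)$", "",
                       basename(unlist(cfg$inputs$tracks)))
  cm <- normalize_counts(count_matrix(tracks, windows))
  combos <- utils::combn(colnames(cm$raw), 2L)
  corr <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    ct <- correlate_tracks(cm, combos[1L, i], combos[2L, i],
                           pseudocount = p$pseudocount %||% 1)
    data.frame(track_x = combos[1L, i], track_y = combos[2L, i],
               slope = ct$slope, intercept = ct$intercept, r = ct$r,
               n = ct$n, stringsAsFactors = FALSE)
  }))
  hm <- rank_heatmap_matrix(cm, p$rank_by %||% colnames(cm$raw)[[1L]],
                            upper_pct = p$winsor %||% 99)
  counts_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(cm$windows)),
    start = GenomicRanges::start(cm$windows) - 1,
    end = GenomicRanges::end(cm$windows), cm$normalized,
    check.names = FALSE)
  list(write_tsv_atomic(counts_df, cfg$output_dir, "counts.tsv"),
       write_tsv_atomic(corr, cfg$output_dir, "correlation.tsv"),
       write_tsv_atomic(as.data.frame(hm$matrix), cfg$output_dir,
                        "heatmap.tsv"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
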