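#' Read a (possibly multi-model) PDB file into a structure ensemble
#'
#' Wraps [bio3d::read.pdb()]; one entry per `MODEL` block (a single model
#' when the file has none). Water (`HOH`/`WAT`/`DOD`) `HETATM` records are
#' excluded by default. Coordinate fields are pre-validated so that a
#' malformed number is reported with its line number rather than silently
#' dropped.
#'
#' @param path Path to a PDB file.
#' @param keep_water Retain water HETATM records.
#' @return An object of class `structure_ensemble`: a list of models, each a
#'   data frame with columns `chain`, `resno`, `resname`, `atom`, `element`,
#'   `x`, `y`, `z` (coordinates in Angstrom, residue numbers as in the file).
#' @export
read_pdb_models <- function(path, keep_water = FALSE) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stopf("no ATOM/HETATM records in '%s'", path)
  for (i in which(is_atom)) {
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- substr(lines[[i]], cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(fld)))) {
        stopf("unparseable coordinate field '%s' at line %d of '%s'",
              trimws(fld), i, path)
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  n_models <- nrow(pdb$xyz)
  keep <- rep(TRUE, nrow(atom))
  if (!keep_water) keep <- !(atom$resid %in% c("HOH", "WAT", "DOD"))
  element <- atom$elesy
  if (any(!nzchar(trimws(element)))) {
    # fall back to first letter of the atom name when the element column
    # is blank (common in minimal model files)
    blank <- !nzchar(trimws(element))
    element[blank] <- substr(trimws(atom$elety[blank]), 1, 1)
  }
  models <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    df <- data.frame(chain = atom$chain, resno = atom$resno,
                     resname = atom$resid, atom = trimws(atom$elety),
                     element = trimws(element),
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     stringsAsFactors = FALSE)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
      stopf("non-finite coordinates in model %d of '%s'", m, path)
    df
  })
  structure(models, class = "structure_ensemble", source = path)
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' Emits fixed-column `ATOM` records, one `MODEL`/`ENDMDL` block per model
#' (no block when the ensemble has a single model). The output re-parses
#' with [read_pdb_models()].
#'
#' @param ensemble A `structure_ensemble` or plain list of atom data frames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(ensemble, path) {
  stopifnot(length(ensemble) >= 1L)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  multi <- length(ensemble) > 1L
  for (m in seq_along(ensemble)) {
    df <- ensemble[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(df)),
      ifelse(nchar(df$atom) < 4, paste0(" ", df$atom), df$atom),
      df$resname, df$chain, df$resno, df$x, df$y, df$z, df$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d model(s), %d atoms, chains %s\n",
              length(x), nrow(x[[1]]),
              paste(unique(x[[1]]$chain), collapse = ",")))
  invisible(x)
}
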