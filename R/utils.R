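# Shared constants and small helpers.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3_TO_1 <- stats::setNames(names(AA3), AA3)

# van der Waals radii (Angstrom); unknown elements fall back to carbon.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' @noRd
vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- unname(VDW_RADII[el])
  if (anyNA(r)) {
    unk <- unique(el[is.na(r)])
    warning("unknown element(s) ", paste(unk, collapse = ", "),
            "; using carbon vdW radius 1.70 A", call. = FALSE)
    r[is.na(r)] <- VDW_RADII[["C"]]
  }
  r
}

#' @noRd
aa3to1 <- function(resname) {
  out <- unname(AA3_TO_1[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == as.integer(x)

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stream tag.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (as.integer(seed) * 1009L + as.integer(h %% 1000003L)) %% 2147483587L
}
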