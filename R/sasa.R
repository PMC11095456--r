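# Shrake-Rupley solvent-accessible surface area.
#
# Sphere points come from a Fibonacci (golden-spiral) lattice, so the
# computation is deterministic: no RNG is involved and results are
# bit-reproducible for a fixed point count.

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' @param n Number of points (>= 1).
#' @return An `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(is_count(n), n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area of a structure model
#'
#' Shrake-Rupley: each atom's sphere of radius `r_vdw + probe_radius` is
#' sampled at `n_points` quasi-uniform points; the accessible fraction is
#' the fraction of points outside every neighbouring atom's expanded
#' sphere, and the atom's SASA is that fraction times the full sphere area
#' `4 * pi * (r_vdw + probe)^2`.
#'
#' @param model Atom data frame (columns `chain`, `resno`, `resname`,
#'   `element`, `x`, `y`, `z`), e.g. one entry of [read_pdb_models()].
#' @param probe_radius Probe radius in Angstrom (water = 1.4).
#' @param n_points Sphere sample points per atom; more points, tighter
#'   accuracy (error roughly O(1/n)).
#' @return Object of class `sasa_result`: list with `atom_sasa` (per-atom
#'   Angstrom^2), `residue_sasa` (data frame chain/resno/resname/sasa),
#'   `probe_radius`, `n_points`.
#' @examples
#' atom <- data.frame(chain = "A", resno = 1, resname = "ALA",
#'                    atom = "CA", element = "C", x = 0, y = 0, z = 0)
#' compute_sasa(atom)$atom_sasa  # 4*pi*(1.7+1.4)^2
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960L) {
  stopifnot(is.data.frame(model))
  if (nrow(model) == 0L) stopf("compute_sasa: model has zero atoms")
  pts <- fibonacci_sphere(n_points)
  radii <- vdw_radius(model$element) + probe_radius
  xyz <- as.matrix(model[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stopf("compute_sasa: non-finite coordinates")
  n <- nrow(xyz)
  atom_sasa <- numeric(n)
  # neighbour lists from the pairwise distance matrix (models here are
  # small; for big structures a cell list would replace this)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    ri <- radii[[i]]
    nb <- which(d2[i, ] < (ri + radii)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      atom_sasa[[i]] <- 4 * pi * ri^2
      next
    }
    sp <- pts * ri
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      free <- free & dj2 > radii[[j]]^2
      if (!any(free)) break
    }
    atom_sasa[[i]] <- mean(free) * 4 * pi * ri^2
  }
  key <- paste(model$chain, model$resno, sep = "\r")
  agg <- rowsum(atom_sasa, key, reorder = FALSE)
  first <- !duplicated(key)
  residue_sasa <- data.frame(chain = model$chain[first],
                             resno = model$resno[first],
                             resname = model$resname[first],
                             sasa = agg[, 1][match(key[first],
                                                   rownames(agg))],
                             stringsAsFactors = FALSE)
  rownames(residue_sasa) <- NULL
  structure(list(atom_sasa = atom_sasa, residue_sasa = residue_sasa,
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}
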