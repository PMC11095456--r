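# Interface residue calling and ensemble interface frequency.
#
# A residue is "interfacial" either because it buries solvent-accessible
# surface on complex formation (buried_sasa, the default, mirroring
# surface-based interface commands in molecular viewers) or because one of
# its heavy atoms sits within a distance cutoff of the partner chain
# (contact). Aggregating calls over a prediction ensemble gives the
# per-residue interface frequency.

#' Call interface residues between two chains of a complex model
#'
#' @param model Atom data frame of the complex (one entry of
#'   [read_pdb_models()]); must contain both chains.
#' @param chain_a,chain_b Chain identifiers.
#' @param method `"buried_sasa"` (residue buries surface area on complex
#'   formation, i.e. isolated-chain SASA minus in-complex SASA exceeds the
#'   cutoff) or `"contact"` (any cross-chain heavy-atom pair within
#'   `contact_cutoff`).
#' @param area_cutoff Buried-area cutoff in Angstrom^2. Calls use the
#'   strict inequality `dSASA > max(area_cutoff, 0.1)`; the 0.1 floor
#'   absorbs numerical noise when the cutoff is 0.
#' @param contact_cutoff Heavy-atom distance cutoff in Angstrom.
#' @param probe_radius,n_points Passed to [compute_sasa()].
#' @return Object of class `interface_result`: list with `chain_pair`,
#'   `residues` (data frame chain/resno/resname/buried_area/contact/
#'   interfacial), `method` and the cutoffs used.
#' @export
call_interface <- function(model, chain_a, chain_b,
                           method = c("buried_sasa", "contact"),
                           area_cutoff = 0, contact_cutoff = 4.0,
                           probe_radius = 1.4, n_points = 960L) {
  method <- match.arg(method)
  chains <- unique(model$chain)
  if (length(chains) < 2L) stopf("call_interface: model has a single chain")
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% chains) stopf("call_interface: chain '%s' not in model", ch)
  }
  sub <- model[model$chain %in% c(chain_a, chain_b), , drop = FALSE]
  key <- paste(sub$chain, sub$resno, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(chain = sub$chain[first], resno = sub$resno[first],
                    resname = sub$resname[first], stringsAsFactors = FALSE)

  # contact flags (computed for both methods; cheap and informative)
  a_idx <- which(sub$chain == chain_a & toupper(sub$element) != "H")
  b_idx <- which(sub$chain == chain_b & toupper(sub$element) != "H")
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  contact_res <- character(0)
  if (length(a_idx) && length(b_idx)) {
    cd <- outer(rowSums(xyz[a_idx, , drop = FALSE]^2),
                rowSums(xyz[b_idx, , drop = FALSE]^2), "+") -
      2 * xyz[a_idx, , drop = FALSE] %*% t(xyz[b_idx, , drop = FALSE])
    hit <- which(cd <= contact_cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      contact_res <- unique(c(key[a_idx[hit[, 1]]], key[b_idx[hit[, 2]]]))
    }
  }
  res$contact <- paste(res$chain, res$resno, sep = "\r") %in% contact_res

  # buried area: isolated-chain SASA minus in-complex SASA, per residue
  sasa_complex <- compute_sasa(sub, probe_radius, n_points)$residue_sasa
  buried <- numeric(nrow(res))
  for (ch in c(chain_a, chain_b)) {
    iso <- compute_sasa(sub[sub$chain == ch, , drop = FALSE],
                        probe_radius, n_points)$residue_sasa
    sel <- res$chain == ch
    m_iso <- iso$sasa[match(res$resno[sel], iso$resno)]
    m_cx <- sasa_complex$sasa[match(paste(ch, res$resno[sel]),
                                    paste(sasa_complex$chain,
                                          sasa_complex$resno))]
    buried[sel] <- m_iso - m_cx
  }
  res$buried_area <- buried
  res$interfacial <- if (method == "buried_sasa") {
    res$buried_area > max(area_cutoff, 0.1)
  } else {
    res$contact
  }
  structure(list(chain_pair = c(chain_a, chain_b), residues = res,
                 method = method, area_cutoff = area_cutoff,
                 contact_cutoff = contact_cutoff),
            class = "interface_result")
}

#' Interface frequency across a structure ensemble
#'
#' For every residue of the two chains, the fraction of ensemble models in
#' which the residue is called interfacial — the per-residue interface
#' frequency plotted against residue number when comparing predicted
#' heterodimer ensembles.
#'
#' @param ensemble `structure_ensemble` (all models must share chain ids
#'   and residue numbering).
#' @param chain_a,chain_b Chain identifiers.
#' @param ... Passed to [call_interface()] (`method`, cutoffs, ...).
#' @return Data frame of class `interface_frequency` with columns `chain`,
#'   `resno`, `resname`, `count`, `n_models`, `frequency`.
#' @export
ensemble_interface_frequency <- function(ensemble, chain_a, chain_b, ...) {
  stopifnot(length(ensemble) >= 1L)
  ref <- NULL
  counts <- NULL
  for (m in seq_along(ensemble)) {
    ir <- call_interface(ensemble[[m]], chain_a, chain_b, ...)$residues
    ids <- paste(ir$chain, ir$resno, sep = "\r")
    if (is.null(ref)) {
      ref <- ir[, c("chain", "resno", "resname")]
      ref_ids <- ids
      counts <- integer(nrow(ref))
    } else if (!identical(ids, ref_ids)) {
      bad <- union(setdiff(ids, ref_ids), setdiff(ref_ids, ids))
      stopf("inconsistent residue numbering across models: %s",
            paste(gsub("\r", ":", bad), collapse = ", "))
    }
    counts <- counts + ir$interfacial
  }
  out <- data.frame(ref, count = counts, n_models = length(ensemble),
                    frequency = counts / length(ensemble),
                    stringsAsFactors = FALSE)
  class(out) <- c("interface_frequency", "data.frame")
  out
}

#' Consensus interaction segments from an interface-frequency table
#'
#' Maximal runs of consecutive residue numbers whose interface frequency
#' meets `threshold`, at least `min_run` residues long — e.g. the PLDLS
#' docking segment emerging from an ensemble of predicted complexes.
#'
#' @param freq `interface_frequency` table.
#' @param chain Chain identifier to scan.
#' @param threshold Minimum frequency (inclusive).
#' @param min_run Minimum run length in residues.
#' @return Data frame with `chain`, `start_res`, `end_res`, `length`,
#'   `segment` (one-letter sequence of the run) and `mean_frequency`.
#' @export
consensus_segments <- function(freq, chain, threshold = 0.5, min_run = 3L) {
  tab <- freq[freq$chain == chain, , drop = FALSE]
  if (nrow(tab) == 0L) stopf("chain '%s' not covered by frequency table",
                             chain)
  tab <- tab[order(tab$resno), , drop = FALSE]
  hot <- tab$frequency >= threshold
  out <- list()
  i <- 1L
  n <- nrow(tab)
  while (i <= n) {
    if (!hot[[i]]) { i <- i + 1L; next }
    j <- i
    while (j < n && hot[[j + 1L]] && tab$resno[[j + 1L]] ==
           tab$resno[[j]] + 1L) j <- j + 1L
    if (j - i + 1L >= min_run) {
      out[[length(out) + 1L]] <- data.frame(
        chain = chain, start_res = tab$resno[[i]], end_res = tab$resno[[j]],
        length = j - i + 1L,
        segment = paste(aa3to1(tab$resname[i:j]), collapse = ""),
        mean_frequency = mean(tab$frequency[i:j]),
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (length(out) == 0L) {
    return(data.frame(chain = character(), start_res = integer(),
                      end_res = integer(), length = integer(),
                      segment = character(), mean_frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect cross-chain hydrogen bonds by geometric criteria
#'
#' Donor and acceptor atoms are nitrogens and oxygens; a pair qualifies
#' when the donor-acceptor distance is at most `d_max` and the angle at the
#' donor (antecedent-donor-acceptor, using the nearest bonded heavy atom of
#' the donor's residue as antecedent) is at least `angle_min`. Models
#' without hydrogens are the norm for predicted structures, so the
#' heavy-atom angle is the criterion; a donor with no antecedent within
#' bonding distance passes on distance alone.
#'
#' @param model Atom data frame of the complex.
#' @param chain_a,chain_b Chain identifiers.
#' @param d_max Donor-acceptor distance cutoff (Angstrom).
#' @param angle_min Minimum donor angle (degrees).
#' @return Data frame with donor/acceptor chain, residue, atom, `distance`
#'   and `angle` (NA when no antecedent exists).
#' @export
detect_hbonds <- function(model, chain_a, chain_b, d_max = 3.5,
                          angle_min = 120) {
  for (ch in c(chain_a, chain_b)) {
    if (!ch %in% model$chain) stopf("detect_hbonds: chain '%s' absent", ch)
  }
  xyz <- as.matrix(model[, c("x", "y", "z")])
  is_no <- toupper(model$element) %in% c("N", "O")
  empty <- data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (dir in list(c(chain_a, chain_b), c(chain_b, chain_a))) {
    don <- which(model$chain == dir[[1]] & is_no)
    acc <- which(model$chain == dir[[2]] & is_no)
    for (d in don) {
      dd <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[d, ])^2))
      for (k in which(dd <= d_max)) {
        a <- acc[[k]]
        # antecedent: nearest heavy atom bonded to the donor (same residue)
        same <- which(model$chain == model$chain[[d]] &
                        model$resno == model$resno[[d]] &
                        toupper(model$element) != "H" &
                        seq_len(nrow(model)) != d)
        ang <- NA_real_
        ok <- TRUE
        if (length(same)) {
          ds <- sqrt(colSums((t(xyz[same, , drop = FALSE]) - xyz[d, ])^2))
          cand <- same[ds < 2.0]
          if (length(cand)) {
            ante <- cand[[which.min(ds[ds < 2.0])]]
            v1 <- xyz[ante, ] - xyz[d, ]
            v2 <- xyz[a, ] - xyz[d, ]
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                       (sqrt(sum(v1^2)) *
                                          sqrt(sum(v2^2)))))) * 180 / pi
            ok <- ang >= angle_min
          }
        }
        if (ok) {
          rows[[length(rows) + 1L]] <- data.frame(
            donor_chain = model$chain[[d]], donor_resno = model$resno[[d]],
            donor_atom = model$atom[[d]], acceptor_chain = model$chain[[a]],
            acceptor_resno = model$resno[[a]],
            acceptor_atom = model$atom[[a]], distance = dd[[k]], angle = ang,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}
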