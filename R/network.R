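# Protein-complex enrichment and the co-membership cosine network.
#
# A complex database (CORUM-like) maps complex ids to member proteins.
# Enrichment of a hit list is the hypergeometric upper tail per complex
# with Benjamini-Hochberg adjustment; the network weights protein pairs by
# the cosine similarity of their binary complex-membership vectors, with
# Louvain communities and a Fruchterman-Reingold layout.

#' Read a complex membership database
#'
#' @param path TSV file: `complex_id <tab> member;member;...`. Ignored when
#'   `text` is given.
#' @param text Optional character scalar of TSV text.
#' @return Object of class `complex_db`: list with `complexes` (named list
#'   of member vectors) and `membership` (binary proteins x complexes
#'   matrix).
#' @export
read_complex_db <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stopf("complex DB format error at line %d", which(lengths(fields) < 2L)[1])
  ids <- vapply(fields, `[[`, character(1), 1L)
  members <- lapply(fields, function(f) {
    m <- unique(strsplit(f[[2L]], ";", fixed = TRUE)[[1]])
    m[nzchar(m)]
  })
  names(members) <- ids
  complex_db(members)
}

#' Build a complex database from a membership list
#'
#' @param complexes Named list, complex id to character vector of members.
#' @return A `complex_db` object.
#' @export
complex_db <- function(complexes) {
  stopifnot(is.list(complexes), !is.null(names(complexes)))
  if (any(lengths(complexes) == 0L))
    stopf("empty complex(es): %s",
          paste(names(complexes)[lengths(complexes) == 0L], collapse = ", "))
  proteins <- sort(unique(unlist(complexes, use.names = FALSE)))
  m <- matrix(0L, length(proteins), length(complexes),
              dimnames = list(proteins, names(complexes)))
  for (j in seq_along(complexes)) m[complexes[[j]], j] <- 1L
  structure(list(complexes = complexes, membership = m),
            class = "complex_db")
}

#' Write a complex database to TSV
#'
#' @param db A `complex_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complex_db <- function(db, path) {
  writeLines(paste(names(db$complexes),
                   vapply(db$complexes, paste, character(1), collapse = ";"),
                   sep = "\t"), path)
  invisible(path)
}

#' Protein-complex enrichment of a hit list
#'
#' Hypergeometric upper-tail test per complex: with universe size `N`,
#' complex size `K`, hit-list size `n` and overlap `k`, the p-value is
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. P-values are BH-adjusted
#' across all complexes tested.
#'
#' @param hits Character vector of hit protein ids.
#' @param db A `complex_db`.
#' @param universe Background protein set; defaults to all proteins in the
#'   database.
#' @return Data frame ordered by `p`: `complex_id`, `k`, `K`, `n`, `N`,
#'   `fold` (= `(k/n) / (K/N)`), `p`, `q`.
#' @export
complex_enrichment <- function(hits, db, universe = NULL) {
  stopifnot(inherits(db, "complex_db"))
  hits <- unique(hits)
  if (length(hits) == 0L) stopf("empty hit list")
  if (is.null(universe)) universe <- rownames(db$membership)
  missing <- setdiff(hits, universe)
  if (length(missing))
    stopf("hit(s) not in universe: %s", paste(missing, collapse = ", "))
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(db$complexes), function(cid) {
    members <- intersect(db$complexes[[cid]], universe)
    K <- length(members)
    k <- length(intersect(members, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(complex_id = cid, k = k, K = K, n = n, N = N,
               fold = if (K > 0) (k / n) / (K / N) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$complex_id), , drop = FALSE]
}

#' Cosine co-membership weights between proteins
#'
#' Edge weight between two proteins is the cosine similarity of their
#' binary complex-membership vectors; zero-weight pairs are omitted.
#'
#' @param db A `complex_db`.
#' @param nodes Protein ids to include as nodes.
#' @param as Return `"similarity"` (default) weights or `"distance"`
#'   (`1 - similarity`).
#' @return Data frame edge list: `from`, `to`, `weight`.
#' @export
cosine_cooccurrence <- function(db, nodes,
                                as = c("similarity", "distance")) {
  as <- match.arg(as)
  stopifnot(inherits(db, "complex_db"))
  nodes <- unique(nodes)
  absent <- setdiff(nodes, rownames(db$membership))
  if (length(absent)) {
    warning("node(s) absent from complex DB excluded: ",
            paste(absent, collapse = ", "), call. = FALSE)
    nodes <- setdiff(nodes, absent)
  }
  m <- db$membership[nodes, , drop = FALSE]
  cp <- tcrossprod(m)
  nrm <- sqrt(diag(cp))
  w <- cp / outer(nrm, nrm)
  w[!is.finite(w)] <- 0
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  weight <- w[idx]
  if (as == "distance") weight <- 1 - weight
  data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
             weight = weight, stringsAsFactors = FALSE)
}

#' @noRd
edges_to_igraph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (igraph::vcount(g) == 0L) stopf("empty graph")
  g
}

#' Louvain community detection
#'
#' @param edges Edge-list data frame (`from`, `to`, `weight`) or an igraph
#'   object.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed (Louvain's node sweep order is randomized).
#' @param nodes Optional vertex table (first column = id) so isolated
#'   nodes are retained.
#' @return Named integer vector: community label per node.
#' @export
detect_communities <- function(edges, resolution = 1, seed = 1L,
                               nodes = NULL) {
  g <- if (inherits(edges, "igraph")) edges else
    edges_to_igraph(edges, nodes)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  stats::setNames(as.integer(igraph::membership(cl)),
                  igraph::V(g)$name)
}

#' Fruchterman-Reingold graph layout
#'
#' @param edges Edge-list data frame or igraph object.
#' @param seed RNG seed (layout is deterministic given the seed).
#' @param iterations Layout iterations.
#' @param nodes Optional vertex table for isolated nodes.
#' @return Data frame `node`, `x`, `y`; a single node sits at the origin.
#' @export
layout_graph <- function(edges, seed = 1L, iterations = 50L, nodes = NULL) {
  g <- if (inherits(edges, "igraph")) edges else
    edges_to_igraph(edges, nodes)
  if (igraph::vcount(g) == 1L) {
    return(data.frame(node = igraph::V(g)$name, x = 0, y = 0,
                      stringsAsFactors = FALSE))
  }
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = iterations)
  data.frame(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

#' Build the full co-complex network
#'
#' Convenience wrapper producing edges, communities and layout in one
#' object, with optional per-node fold-enrichment annotation (dot size in
#' the usual network rendering).
#'
#' @param db A `complex_db`.
#' @param nodes Protein ids (e.g. the IP-MS enriched set).
#' @param fold Optional named numeric vector of fold enrichments.
#' @param resolution,seed,iterations See [detect_communities()] and
#'   [layout_graph()].
#' @return Object of class `cocomplex_graph`: list with `edges`, `nodes`
#'   (data frame node/community/x/y/fold).
#' @export
build_cocomplex_graph <- function(db, nodes, fold = NULL, resolution = 1,
                                  seed = 1L, iterations = 50L) {
  edges <- cosine_cooccurrence(db, nodes)
  present <- intersect(nodes, rownames(db$membership))
  vtab <- data.frame(name = present, stringsAsFactors = FALSE)
  comm <- detect_communities(edges, resolution, seed, nodes = vtab)
  lay <- layout_graph(edges, seed, iterations, nodes = vtab)
  ntab <- data.frame(node = names(comm), community = unname(comm),
                     stringsAsFactors = FALSE)
  ntab <- merge(ntab, lay, by = "node", sort = TRUE)
  ntab$fold <- if (!is.null(fold)) unname(fold[ntab$node]) else NA_real_
  structure(list(edges = edges, nodes = ntab), class = "cocomplex_graph")
}
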