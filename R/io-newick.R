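#' Serialize a tree to a Newick string
#'
#' Wraps [ape::write.tree()] with duplicate-label checking and support for
#' the degenerate single-leaf tree (serialized as `"label;"`).
#'
#' @param tree An [ape::phylo] object, or a single leaf label.
#' @return A Newick string terminated by `";"`.
#' @export
write_newick <- function(tree) {
  if (is.character(tree) && length(tree) == 1L) return(paste0(tree, ";"))
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate leaf labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  ape::write.tree(tree)
}

#' Parse a Newick string into a tree
#'
#' @param text A Newick string.
#' @return An [ape::phylo] object (or the leaf label for a single-leaf
#'   string).
#' @export
read_newick <- function(text) {
  txt <- trimws(text)
  if (!grepl("\\(", txt)) return(sub(";$", "", txt))
  ape::read.tree(text = txt)
}
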