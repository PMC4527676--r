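#' Read a phylogenetic tree from Newick text
#'
#' Thin validation wrapper over [ape::read.tree()]. Internal node labels are
#' interpreted as branch support values (integer percent) where numeric.
#'
#' @param text Newick text (single string) or a path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text) {
  if (length(text) == 1 && !grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort_globinkit("unbalanced parentheses in Newick text", "globinkit_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tree)) {
    abort_globinkit("could not parse Newick text", "globinkit_parse_error")
  }
  if (length(tree$tip.label) < 2) {
    abort_globinkit("tree must have at least 2 leaves", "globinkit_bad_input")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort_globinkit("leaf labels must be unique", "globinkit_bad_input")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort_globinkit("branch lengths must be non-negative", "globinkit_bad_input")
  }
  tree
}

#' Write a phylogenetic tree as Newick text
#'
#' Branch support values (if present as `node.label`) are written as internal
#' node labels. Branch lengths are preserved to at least 6 significant digits.
#'
#' @param tree An [ape::phylo] tree.
#' @return A single Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) {
    abort_globinkit("tree must have at least 2 leaves", "globinkit_bad_input")
  }
  ape::write.tree(tree, digits = 10)
}
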