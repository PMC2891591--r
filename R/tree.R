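#' Read a rooted binary phylogenetic tree
#'
#' Parses a Newick file with `ape`. Every branch must carry a length. An
#' unrooted tree presenting as a root trifurcation is resolved into a rooted
#' binary tree by inserting a zero-length internal edge; for the reversible
#' substitution models used here the likelihood does not depend on the root
#' placement, so the resolution is harmless. Polytomies anywhere else are
#' rejected.
#'
#' @param path Newick file path (or a literal Newick string via `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return A rooted, binary `phylo` object with branch lengths.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) {
    ape::read.tree(text = text)
  } else {
    if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
    ape::read.tree(path)
  }
  if (is.null(tr)) stop("could not parse Newick tree", call. = FALSE)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("tree is missing branch lengths", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tree leaf labels", call. = FALSE)
  }
  n_children <- tabulate(tr$edge[, 1], nbins = ape::Ntip(tr) + tr$Nnode)
  internal <- n_children[n_children > 0]
  root <- ape::Ntip(tr) + 1L
  non_root_poly <- which(n_children > 2)
  non_root_poly <- setdiff(non_root_poly, root)
  if (length(non_root_poly)) {
    stop("tree has polytomies beyond the root; only a root trifurcation ",
         "(unrooted tree) is resolved automatically", call. = FALSE)
  }
  if (n_children[root] == 3) {
    tr <- ape::multi2di(tr, random = FALSE)  # adds one zero-length edge
  } else if (n_children[root] > 3) {
    stop("root has ", n_children[root], " children; cannot resolve", call. = FALSE)
  }
  if (!ape::is.binary(tr)) stop("tree is not binary", call. = FALSE)
  tr
}

#' Total tree length
#'
#' Sum of all branch lengths; the standard proxy for the evolutionary
#' diversity spanned by an alignment.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Numeric scalar.
#' @export
total_tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  sum(tree$edge.length)
}
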