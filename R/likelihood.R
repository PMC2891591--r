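# Vectorised Felsenstein pruning.
#
# leafmats: list indexed by tip number, each an nstate x m matrix of leaf
# vectors (m independent columns evaluated simultaneously). Per-column
# scaling by the running maximum keeps products in range on deep trees; the
# accumulated log scale is added back at the root, so the returned
# log-likelihoods are exact regardless of tree depth.
prune_loglik <- function(leafmats, tree, model) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  m <- ncol(leafmats[[1]])
  tr <- stats::reorder(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  vecs <- vector("list", ntip + nnode)
  vecs[seq_len(ntip)] <- leafmats
  logscale <- numeric(m)
  parents <- unique(edge[, 1])  # postorder: children always before parents
  children_of <- split(seq_len(nrow(edge)), edge[, 1])
  for (nd in parents) {
    M <- 1
    for (e in children_of[[as.character(nd)]]) {
      child <- edge[e, 2]
      M <- M * (transition_matrix(model, elen[e]) %*% vecs[[child]])
    }
    # any positive per-column factor prevents underflow; column sums are
    # cheaper than column maxima and never zero unless the column is all zero
    scl <- .colSums(M, nrow(M), m)
    scl[scl <= 0] <- 1  # all-zero column: likelihood 0, log handled at root
    M <- M / rep(scl, each = nrow(M))
    logscale <- logscale + log(scl)
    vecs[[nd]] <- M
  }
  root <- ntip + 1L
  lik <- colSums(model$pi * vecs[[root]])
  if (any(lik <= 0)) {
    warning("zero column likelihood encountered", call. = FALSE)
  }
  log(lik) + logscale
}

# map alignment rows into tip order: list of per-tip character matrices
tip_char_rows <- function(aln, tree) {
  mat <- alignment_matrix(aln)
  ridx <- match(tree$tip.label, aln$ids)
  if (anyNA(ridx)) {
    stop("tree leaves missing from alignment; run match_leaves() first",
         call. = FALSE)
  }
  mat[ridx, , drop = FALSE]
}

#' Log-likelihood of unpaired alignment columns
#'
#' Felsenstein pruning of single columns under the 4-state unpaired model.
#'
#' @param aln An `rna_alignment`.
#' @param tree Rooted binary `phylo` whose leaves match the alignment rows.
#' @param model The unpaired `evo_model`.
#' @param cols Integer vector of 1-based columns (default: all).
#' @return Numeric vector of natural-log likelihoods, one per column.
#' @export
column_loglik_unpaired <- function(aln, tree, model, cols = seq_len(aln$n_cols)) {
  chars <- tip_char_rows(aln, tree)[, cols, drop = FALSE]
  leafmats <- lapply(seq_len(nrow(chars)), function(r) {
    leaf_vector_unpaired(chars[r, ])
  })
  prune_loglik(leafmats, tree, model)
}

#' Log-likelihood of base-paired column pairs
#'
#' Felsenstein pruning of ordered column pairs under the 16-state paired
#' model, with the one-sided-gap semantics of [leaf_vector_paired()].
#'
#' @param aln An `rna_alignment`.
#' @param tree Rooted binary `phylo` whose leaves match the alignment rows.
#' @param model The paired `evo_model`.
#' @param pairs `m x 2` matrix of 1-based column pairs `(i, j)`.
#' @return Numeric vector of natural-log likelihoods, one per pair.
#' @export
column_loglik_paired <- function(aln, tree, model, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  chars <- tip_char_rows(aln, tree)
  leafmats <- lapply(seq_len(nrow(chars)), function(r) {
    leaf_vector_paired(chars[r, pairs[, 1]], chars[r, pairs[, 2]])
  })
  prune_loglik(leafmats, tree, model)
}

#' Column likelihood (probability scale)
#'
#' Convenience wrapper returning `exp` of the pruning log-likelihood for a
#' single unpaired column or a single column pair.
#'
#' @param aln,tree As in [column_loglik_unpaired()].
#' @param models Model list from [load_default_models()].
#' @param col Unpaired column index, or `NULL`.
#' @param pair Length-2 column pair, or `NULL`. Exactly one of `col`/`pair`
#'   must be given.
#' @return Likelihood in `(0, 1]`.
#' @export
column_likelihood <- function(aln, tree, models, col = NULL, pair = NULL) {
  if (is.null(col) == is.null(pair)) {
    stop("give exactly one of `col` or `pair`", call. = FALSE)
  }
  if (!is.null(col)) {
    exp(column_loglik_unpaired(aln, tree, models$unpaired, col))
  } else {
    exp(column_loglik_paired(aln, tree, models$paired,
                             matrix(pair, ncol = 2)))
  }
}

#' Score conserved helices by length-normalised log-likelihood ratio
#'
#' For a helix `h` with `L` column pairs, the score is
#' \deqn{S(h) = \frac{1}{L}\Big[\sum_k \log P_{paired}(i_k, j_k)
#'   - \sum_k \big(\log P_{unpaired}(i_k) + \log P_{unpaired}(j_k)\big)\Big]}
#' contrasting the hypothesis that the helix columns co-evolve as base pairs
#' against the hypothesis that they evolve independently as unpaired columns
#' (natural log; division by `L` makes scores comparable across helix
#' lengths). Likelihoods are shared across helices, so each distinct column
#' and column pair is pruned once.
#'
#' @param helices Tibble from [collect_conserved_helices()].
#' @param aln An `rna_alignment`.
#' @param tree Rooted binary `phylo` matching the alignment.
#' @param models Model list from [load_default_models()].
#' @return `helices` with a `score` column appended.
#' @export
score_helices <- function(helices, aln, tree, models) {
  if (!nrow(helices)) {
    helices$score <- numeric()
    return(helices)
  }
  allpairs <- do.call(rbind, helices$pairs)
  hidx <- rep(seq_len(nrow(helices)), helices$length)
  code <- (allpairs[, 1] - 1) * aln$n_cols + allpairs[, 2]  # integer pair key
  upairs <- allpairs[!duplicated(code), , drop = FALSE]
  ucode <- code[!duplicated(code)]
  ucols <- sort(unique(as.vector(upairs)))
  lu <- numeric(aln$n_cols)
  lu[ucols] <- column_loglik_unpaired(aln, tree, models$unpaired, ucols)
  lp <- column_loglik_paired(aln, tree, models$paired, upairs)
  contrib <- lp[match(code, ucode)] - lu[allpairs[, 1]] - lu[allpairs[, 2]]
  helices$score <- as.vector(rowsum(contrib, hidx)) / helices$length
  helices
}
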