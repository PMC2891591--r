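# Independent brute-force oracles and small fixture builders.

CANON <- c("AU", "UA", "GC", "CG", "GU", "UG")

is_canon <- function(x, y) paste0(x, y) %in% CANON

# Exhaustive helix search: all (p, q, len) triples with every rung a
# consensus pair, the innermost pair enclosing >= min_loop nucleotides, and
# maximality outward and inward. Independent of the anti-diagonal scan.
brute_force_helices <- function(sequence, min_len = 4, min_loop = 3) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  ok <- function(p, q) {
    p >= 1 && q <= n && q - p >= min_loop + 1 && is_canon(chars[p], chars[q])
  }
  out <- list()
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (!ok(p, q)) next
      for (len in 1:floor(n / 2)) {
        rungs_ok <- all(vapply(0:(len - 1),
                               function(k) ok(p + k, q - k), logical(1)))
        if (!rungs_ok) next
        outward <- p > 1 && q < n && is_canon(chars[p - 1], chars[q + 1])
        inward <- ok(p + len, q - len)
        if (len >= min_len && !outward && !inward) {
          out[[length(out) + 1L]] <- cbind(p = p + 0:(len - 1),
                                           q = q - 0:(len - 1))
        }
      }
    }
  }
  out
}

helix_key_set <- function(pairs_list) {
  sort(vapply(pairs_list, function(m) paste(m[, 1], m[, 2], collapse = ";"),
              character(1)))
}

# Exhaustive Felsenstein oracle: sum the full joint probability over all
# internal-node state assignments. Only feasible for tiny trees.
brute_force_loglik <- function(leafmats, tree, model) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  k <- model$nstate
  m <- ncol(leafmats[[1]])
  edge <- tree$edge
  elen <- tree$edge.length
  P <- lapply(seq_len(nrow(edge)),
              function(e) transat::transition_matrix(model, elen[e]))
  assignments <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  total <- matrix(0, nrow(assignments), m)
  for (a in seq_len(nrow(assignments))) {
    states <- assignments[a, ]  # states[v] for internal node ntip + v
    w <- rep(model$pi[states[1]], m)  # root prior (root is node ntip + 1)
    for (e in seq_len(nrow(edge))) {
      par_state <- states[edge[e, 1] - ntip]
      child <- edge[e, 2]
      w <- w * if (child <= ntip) {
        colSums(P[[e]][par_state, ] * leafmats[[child]])
      } else {
        rep(P[[e]][par_state, states[child - ntip]], m)
      }
    }
    total[a, ] <- w
  }
  log(colSums(total))
}

# random rooted binary tree with exponential branch lengths
random_binary_tree <- function(n_leaves, mean_bl = 0.4) {
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_bl)
  tr$tip.label <- paste0("s", seq_len(n_leaves))
  tr
}

# re-root a rooted tree at a random position of its unrooted version,
# resolving to binary; total length and leaf set are preserved
reroot_random <- function(tr) {
  utr <- ape::unroot(tr)
  nd <- sample(ape::Ntip(utr) + 2:utr$Nnode, 1)
  transat:::validate_tree(ape::root(utr, node = nd, resolve.root = TRUE))
}

# random gapped alignment over given ids
random_alignment <- function(n_rows, n_cols, gap_prob = 0.1,
                             ids = paste0("s", seq_len(n_rows))) {
  seqs <- vapply(seq_len(n_rows), function(i) {
    paste(sample(c("A", "C", "G", "U", "-"), n_cols, replace = TRUE,
                 prob = c(rep((1 - gap_prob) / 4, 4), gap_prob)),
          collapse = "")
  }, character(1))
  # avoid the (vanishingly unlikely) all-gap row
  seqs <- vapply(seqs, function(s) {
    if (gsub("-", "", s) == "") sub("-", "A", s) else s
  }, character(1), USE.NAMES = FALSE)
  rna_alignment(ids, seqs)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
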