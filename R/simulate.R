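#' Balanced binary tree with equal branch lengths
#'
#' Builds a maximally balanced rooted binary tree (leaf depths differ by at
#' most one) with `n_seqs` leaves labelled `t1..tn`, and gives each of its
#' `2 n_seqs - 2` edges the length `total_length / (2 n_seqs - 2)`, so the
#' total tree length is exactly `total_length`.
#'
#' @param n_seqs Number of leaves (>= 2).
#' @param total_length Desired total tree length.
#' @return A rooted binary `phylo`.
#' @export
build_balanced_tree <- function(n_seqs, total_length) {
  if (n_seqs < 2) stop("need at least 2 sequences", call. = FALSE)
  if (total_length < 0) stop("total_length must be non-negative", call. = FALSE)
  nwk <- function(lo, hi) {
    if (lo == hi) return(paste0("t", lo))
    mid <- lo + (hi - lo + 1L) %/% 2L - 1L
    paste0("(", nwk(lo, mid), ",", nwk(mid + 1L, hi), ")")
  }
  tr <- ape::read.tree(text = paste0(nwk(1L, as.integer(n_seqs)), ";"))
  tr$edge.length <- rep(total_length / (2 * n_seqs - 2), nrow(tr$edge))
  tr
}

#' Random nested secondary structure for simulation
#'
#' Greedily places helices of at least `min_helix` pairs with hairpin loops
#' of at least `min_loop` nucleotides into random free intervals (including
#' intervals inside already-placed loops, so multiloop-like nestings arise)
#' until roughly `target_pair_fraction` of positions are paired or no
#' interval can host another helix. A stand-in for curated structure
#' databases; uses the current RNG state.
#'
#' @param length Sequence length (>= 12).
#' @param target_pair_fraction Fraction of positions to involve in pairs.
#' @param min_helix Minimum helix length in pairs.
#' @param max_helix Maximum helix length in pairs.
#' @param min_loop Minimum hairpin-loop size.
#' @return An `rna_structure` over `1..length`.
#' @export
random_structure <- function(length, target_pair_fraction = 0.5,
                             min_helix = 4, max_helix = 10, min_loop = 3) {
  if (length < 12) stop("length must be at least 12", call. = FALSE)
  min_span <- 2 * min_helix + min_loop
  segs <- list(c(1L, as.integer(length)))
  ii <- integer(); jj <- integer()
  repeat {
    fits <- vapply(segs, function(s) s[2] - s[1] + 1L >= min_span, logical(1))
    if (2 * length(ii) / length >= target_pair_fraction || !any(fits)) break
    sample1 <- function(v) v[sample.int(length(v), 1)]  # no 1:x surprise
    k <- which(fits)[sample.int(sum(fits), 1)]
    s <- segs[[k]]; seglen <- s[2] - s[1] + 1L
    l <- sample1(min_helix:min(max_helix, (seglen - min_loop) %/% 2L))
    g <- sample1(min_loop:(seglen - 2L * l))         # loop size
    a <- s[1] + sample.int(seglen - 2L * l - g + 1L, 1) - 1L  # outer 5' pos
    b <- a + 2L * l + g - 1L                          # outer 3' pos
    ii <- c(ii, a + 0:(l - 1L)); jj <- c(jj, b - 0:(l - 1L))
    segs[[k]] <- NULL
    new_segs <- list(c(s[1], a - 1L), c(a + l, b - l), c(b + 1L, s[2]))
    for (ns in new_segs) if (ns[2] >= ns[1]) segs[[length(segs) + 1L]] <- ns
  }
  rna_structure(ii, jj, length)
}

#' Evolve a structured alignment down a balanced tree
#'
#' Simulates gapless sequences on the leaves of a balanced binary tree under
#' the package's substitution models: base-paired positions (given by
#' `structure`) evolve jointly as one 16-state dinucleotide site, unpaired
#' positions as independent 4-state sites. The root is drawn from the
#' respective equilibrium distribution and states are propagated from root to
#' leaves using the transition matrices of the shared branch length. There is
#' no indel process. Pseudoknotted structures are handled like nested ones:
#' sites are independent given the structure.
#'
#' @param structure An `rna_structure` defining the paired positions.
#' @param n_seqs Number of sequences (tree leaves).
#' @param total_tree_length Total branch length of the balanced tree.
#' @param models Model list from [load_default_models()].
#' @param seed Optional integer seed.
#' @return List with elements `alignment` (an `rna_alignment` carrying the
#'   generating structure as `ss_cons`), `tree` (the balanced `phylo`), and
#'   `structure`.
#' @export
evolve_alignment <- function(structure, n_seqs, total_tree_length,
                             models = load_default_models(), seed = NULL) {
  stopifnot(inherits(structure, "rna_structure"), n_seqs >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_cols <- attr(structure, "n_cols")
  tree <- build_balanced_tree(n_seqs, total_tree_length)
  paired <- cbind(structure$i, structure$j)
  unpaired <- setdiff(seq_len(n_cols), as.vector(paired))
  n_up <- length(unpaired); n_pp <- nrow(paired)

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  up_states <- matrix(NA_integer_, ntip + nnode, n_up)
  pp_states <- matrix(NA_integer_, ntip + nnode, n_pp)
  root <- ntip + 1L
  if (n_up) up_states[root, ] <- sample.int(4, n_up, replace = TRUE,
                                            prob = models$unpaired$pi)
  if (n_pp) pp_states[root, ] <- sample.int(16, n_pp, replace = TRUE,
                                            prob = models$paired$pi)
  sample_children <- function(parent_states, P) {
    out <- integer(length(parent_states))
    for (a in unique(parent_states)) {
      w <- parent_states == a
      out[w] <- sample.int(ncol(P), sum(w), replace = TRUE, prob = P[a, ])
    }
    out
  }
  tr <- stats::reorder(tree, "cladewise")  # parents precede children
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; chd <- tr$edge[e, 2]; t <- tr$edge.length[e]
    if (n_up) up_states[chd, ] <- sample_children(
      up_states[par, ], transition_matrix(models$unpaired, t))
    if (n_pp) pp_states[chd, ] <- sample_children(
      pp_states[par, ], transition_matrix(models$paired, t))
  }
  seqs <- vapply(seq_len(ntip), function(tp) {
    chars <- character(n_cols)
    if (n_up) chars[unpaired] <- NUCS[up_states[tp, ]]
    if (n_pp) {
      s <- pp_states[tp, ]
      chars[paired[, 1]] <- NUCS[(s - 1L) %/% 4L + 1L]
      chars[paired[, 2]] <- NUCS[(s - 1L) %% 4L + 1L]
    }
    paste(chars, collapse = "")
  }, character(1))
  aln <- rna_alignment(tree$tip.label, seqs,
                       ss_cons = structure_to_string(structure))
  list(alignment = aln, tree = tree, structure = structure)
}

#' Generate the artificial benchmark data set
#'
#' Reproduces the simulation design used to study how detection performance
#' depends on evolutionary diversity and alignment length. Structures are
#' drawn from [random_structure()] (or supplied), binned by sequence length
#' (100-199 up to 900-999 by default). The *tree experiment* simulates, for
#' each of `structures_per_bin_tree` structures per bin, alignments of
#' `n_seqs` sequences at every total tree length in `tree_lengths`
#' (9 x 10 x 6 = 540 alignments at the defaults). The *length experiment*
#' simulates one alignment per structure for `structures_per_bin_length`
#' structures per bin at total tree length `length_experiment_tree_length`
#' (9 x 50 = 450 alignments at the defaults).
#'
#' @param design `"tree_experiment"`, `"length_experiment"`, or `"both"`.
#' @param seed Integer seed making the whole collection reproducible.
#' @param n_seqs Sequences per alignment (default 10).
#' @param bin_starts Lower bounds of the length bins (width 100).
#' @param structures_per_bin_tree,structures_per_bin_length Structures drawn
#'   per bin for the two experiments (defaults 10 and 50).
#' @param tree_lengths Total tree lengths of the tree experiment.
#' @param length_experiment_tree_length Tree length of the length experiment.
#' @param models Model list from [load_default_models()].
#' @param out_dir Optional directory; when given, each replicate is written
#'   as Stockholm (with the generating structure as `SS_cons`) plus Newick,
#'   along with a `manifest.tsv`.
#' @return A tibble manifest with one row per alignment: `experiment`,
#'   `bin_start`, `structure_id`, `seq_length`, `tree_length`, `n_seqs`, and
#'   list-columns `alignment`, `tree`, `structure`.
#' @export
artificial_dataset_driver <- function(design = c("both", "tree_experiment",
                                                 "length_experiment"),
                                      seed = 1,
                                      n_seqs = 10,
                                      bin_starts = seq(100, 900, by = 100),
                                      structures_per_bin_tree = 10,
                                      structures_per_bin_length = 50,
                                      tree_lengths = c(0.5, 1, 2, 4, 8, 16),
                                      length_experiment_tree_length = 4,
                                      models = load_default_models(),
                                      out_dir = NULL) {
  design <- match.arg(design)
  set.seed(seed)
  rows <- list()
  simulate_block <- function(experiment, per_bin, t_lengths) {
    for (bin in bin_starts) {
      for (sid in seq_len(per_bin)) {
        len <- sample(bin:(bin + 99L), 1)
        struct <- random_structure(len)
        for (tl in t_lengths) {
          sim <- evolve_alignment(struct, n_seqs, tl, models)
          rows[[length(rows) + 1L]] <<- tibble(
            experiment = experiment, bin_start = bin, structure_id = sid,
            seq_length = len, tree_length = tl, n_seqs = n_seqs,
            alignment = list(sim$alignment), tree = list(sim$tree),
            structure = list(struct))
        }
      }
    }
  }
  if (design %in% c("both", "tree_experiment")) {
    simulate_block("tree_experiment", structures_per_bin_tree, tree_lengths)
  }
  if (design %in% c("both", "length_experiment")) {
    simulate_block("length_experiment", structures_per_bin_length,
                   length_experiment_tree_length)
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- sprintf("%s_bin%d_s%02d_T%g", manifest$experiment,
                    manifest$bin_start, manifest$structure_id,
                    manifest$tree_length)
    for (k in seq_len(nrow(manifest))) {
      write_alignment(manifest$alignment[[k]],
                      file.path(out_dir, paste0(stem[k], ".sto")), "stockholm")
      ape::write.tree(manifest$tree[[k]],
                      file.path(out_dir, paste0(stem[k], ".nwk")))
    }
    write.table(
      cbind(file_stem = stem,
            manifest[, c("experiment", "bin_start", "structure_id",
                         "seq_length", "tree_length", "n_seqs")]),
      file.path(out_dir, "manifest.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest
}
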