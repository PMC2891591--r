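#' Optional sequence-only realignment hook
#'
#' The p-value null is ideally built from an alignment that reflects primary
#' sequence conservation only, so that structure-driven alignment patterns do
#' not leak into the shuffles. This hook strips the gaps, writes the
#' sequences to FASTA, runs an external aligner given as a command template
#' containing `{in}` and `{out}` placeholders, and reads the result back.
#' With `command = NULL` (the default) the input alignment is returned
#' unchanged and a message notes that the realignment step was skipped.
#'
#' @param aln An `rna_alignment`.
#' @param command Command template string, e.g.
#'   `"mafft --auto {in} > {out}"`, or `NULL` to skip.
#' @return An `rna_alignment` over the same sequence ids.
#' @export
realign_hook <- function(aln, command = NULL) {
  stopifnot(inherits(aln, "rna_alignment"))
  if (is.null(command)) {
    message("realignment hook disabled; null distribution is built from ",
            "the input alignment as given")
    return(aln)
  }
  if (!grepl("{in}", command, fixed = TRUE) ||
      !grepl("{out}", command, fixed = TRUE)) {
    stop("realign command template must contain {in} and {out}", call. = FALSE)
  }
  fin <- tempfile(fileext = ".fa")
  fout <- tempfile(fileext = ".aln")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  ungapped <- rna_alignment_unchecked_write(aln, fin)
  cmd <- gsub("{out}", fout, gsub("{in}", fin, command, fixed = TRUE),
              fixed = TRUE)
  res <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    hook_error("realign command failed (exit ", status, "): ",
               paste(tail(res, 5), collapse = "\n"))
  }
  if (!file.exists(fout) || file.size(fout) == 0) {
    hook_error("realign command produced no output file")
  }
  out <- tryCatch(read_alignment(fout),
                  error = function(e) hook_error(
                    "could not parse realigner output: ",
                    conditionMessage(e)))
  if (!setequal(out$ids, aln$ids)) {
    hook_error("realigner changed the sequence id set")
  }
  out
}

hook_error <- function(...) {
  stop(structure(class = c("transat_hook_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# write ungapped sequences as FASTA for the external hook
rna_alignment_unchecked_write <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$ids),
                             gsub("-", "", unname(aln$seqs)))), path)
  invisible(path)
}

#' Assign alignment columns to shuffling bins
#'
#' Columns may only be swapped with columns of similar gap composition and
#' primary sequence conservation. The bin key of a column is the pair
#' (number of gaps, conservation bin), where conservation is the relative
#' frequency of the most common non-gap character among the non-gap rows
#' (0 for an all-gap column), discretised into `conservation_bins` equal
#' intervals with 1.0 assigned to the top bin.
#'
#' @param aln An `rna_alignment`.
#' @param conservation_bins Number of conservation intervals (default 10).
#' @return Character vector of bin keys, one per column.
#' @export
bin_columns <- function(aln, conservation_bins = 10) {
  stopifnot(conservation_bins >= 1)
  mat <- alignment_matrix(aln)
  apply(mat, 2, function(col) {
    gaps <- sum(col == "-")
    nong <- col[col != "-"]
    cons <- if (length(nong)) max(tabulate(factor(nong))) / length(nong) else 0
    b <- min(floor(cons * conservation_bins), conservation_bins - 1)
    paste0("g", gaps, ".c", b)
  })
}

#' Shuffle alignment columns within bins
#'
#' Permutes the columns uniformly at random within each bin; the multiset of
#' columns (and hence per-row gap counts per bin, base composition, and
#' conservation profile) is preserved exactly. Columns in singleton bins
#' cannot move. Uses the current RNG state.
#'
#' @param aln An `rna_alignment`.
#' @param bins Bin keys from [bin_columns()] (recomputed when `NULL`).
#' @param conservation_bins Used when `bins` is `NULL`.
#' @return A shuffled `rna_alignment` (any `ss_cons` annotation is dropped).
#' @export
shuffle_alignment <- function(aln, bins = NULL, conservation_bins = 10) {
  if (is.null(bins)) bins <- bin_columns(aln, conservation_bins)
  stopifnot(length(bins) == aln$n_cols)
  perm <- seq_len(aln$n_cols)
  for (idx in split(perm, bins)) {
    if (length(idx) > 1) perm[idx] <- idx[sample.int(length(idx))]
  }
  mat <- alignment_matrix(aln)[, perm, drop = FALSE]
  rna_alignment(aln$ids, apply(mat, 1, paste, collapse = ""))
}

#' Build the null distribution of helix scores from shuffled alignments
#'
#' Generates `n_shuffles` conservation-binned column shuffles of the (
#' optionally realigned) input alignment; in each shuffle, conserved helices
#' are detected and scored exactly as for the real input, and all scores are
#' pooled into one empirical null distribution. Sub-stream seeds for the
#' individual shuffles are drawn up front from `seed`, so the pooled result
#' is reproducible and independent of evaluation order.
#'
#' @param aln An `rna_alignment`.
#' @param tree Rooted binary `phylo` matching the alignment rows.
#' @param models Model list from [load_default_models()].
#' @param n_shuffles Number of shuffled alignments (default 500).
#' @param seed Integer seed for reproducibility.
#' @param conservation_bins Passed to [bin_columns()].
#' @param min_len,min_loop Helix enumeration settings; must equal those used
#'   on the real alignment.
#' @param realign_cmd Optional command template for [realign_hook()].
#' @return A `null_distribution`: list with `scores` (pooled numeric vector),
#'   `n_scores`, `n_shuffles` and `helices_per_shuffle`.
#' @export
build_null_distribution <- function(aln, tree, models, n_shuffles = 500,
                                    seed = NULL, conservation_bins = 10,
                                    min_len = 4, min_loop = 3,
                                    realign_cmd = NULL) {
  stopifnot(n_shuffles >= 1)
  base <- if (is.null(realign_cmd)) {
    suppressMessages(realign_hook(aln, NULL))
  } else {
    realign_hook(aln, realign_cmd)
  }
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_shuffles)
  bins <- bin_columns(base, conservation_bins)
  counts <- integer(n_shuffles)
  scores <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    set.seed(sub_seeds[s])
    shuf <- shuffle_alignment(base, bins)
    h <- collect_conserved_helices(shuf, min_len, min_loop)
    counts[s] <- nrow(h)
    if (nrow(h)) scores[[s]] <- score_helices(h, shuf, tree, models)$score
  }
  pooled <- unlist(scores)
  if (!length(pooled)) {
    stop("no helices found in any shuffled alignment; increase n_shuffles ",
         "or lower min_len", call. = FALSE)
  }
  if (length(pooled) < 1000) {
    warning("null distribution pools only ", length(pooled),
            " scores; p-values are coarse (consider more shuffles)",
            call. = FALSE)
  }
  structure(list(scores = pooled, n_scores = length(pooled),
                 n_shuffles = n_shuffles, helices_per_shuffle = counts),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null distribution:", x$n_scores, "helix scores pooled from",
      x$n_shuffles, "shuffled alignments\n")
  invisible(x)
}

#' Empirical right-tail p-value
#'
#' `p = (#\{null >= score\} + 1) / (n + 1)`: the add-one estimator never
#' returns zero and is conservative, matching the resolution limit of an
#' empirical null. Monotone non-increasing in the score.
#'
#' @param score Numeric vector of helix scores.
#' @param null A `null_distribution`.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_pvalue <- function(score, null) {
  stopifnot(inherits(null, "null_distribution"), null$n_scores >= 1)
  # right-tail counts via the ECDF of the sorted null
  srt <- sort(null$scores)
  ge <- null$n_scores - findInterval(score, srt, left.open = TRUE)
  (ge + 1) / (null$n_scores + 1)
}
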