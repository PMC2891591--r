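#' Detect statistically significant conserved helices
#'
#' The full pipeline: verify that tree leaves and alignment rows match,
#' enumerate candidate helices on every ungapped sequence and project them
#' onto alignment columns, score each conserved helix by the length-normalised
#' paired-vs-unpaired log-likelihood ratio, build an empirical null from
#' conservation-binned column shuffles, and assign right-tail p-values.
#'
#' @param aln An `rna_alignment` (or a path, read with [read_alignment()]).
#' @param tree A rooted binary `phylo` (or a Newick path, read with
#'   [read_tree()]).
#' @param models Model list from [load_default_models()].
#' @param min_helix_len Minimum helix length in base pairs (default 4).
#' @param min_loop Minimum hairpin loop (default 3).
#' @param shuffles Number of shuffled alignments for the null (default 500).
#' @param seed Integer seed for the shuffling.
#' @param conservation_bins Shuffling bins (default 10).
#' @param realign_cmd Optional external realignment command template, see
#'   [realign_hook()].
#' @return A `transat_fit` object; use [tidy()] for the per-helix table,
#'   [glance()] for a one-row summary, [autoplot()] for an arc diagram and
#'   [write_predictions()] for the TSV output.
#' @export
transat_predict <- function(aln, tree, models = load_default_models(),
                            min_helix_len = 4, min_loop = 3, shuffles = 500,
                            seed = NULL, conservation_bins = 10,
                            realign_cmd = NULL) {
  if (is.character(aln)) aln <- read_alignment(aln)
  if (is.character(tree)) tree <- read_tree(tree)
  match_leaves(aln, tree)
  config <- list(min_helix_len = min_helix_len, min_loop = min_loop,
                 shuffles = shuffles, seed = seed,
                 conservation_bins = conservation_bins,
                 realign_cmd = realign_cmd,
                 total_tree_length = total_tree_length(tree))
  helices <- collect_conserved_helices(aln, min_helix_len, min_loop)
  if (!nrow(helices)) {
    warning("no candidate helices found in the alignment", call. = FALSE)
    helices$score <- numeric()
    helices$p_value <- numeric()
    return(new_transat_fit(helices, NULL, config, aln, tree))
  }
  helices <- score_helices(helices, aln, tree, models)
  null <- build_null_distribution(aln, tree, models, n_shuffles = shuffles,
                                  seed = seed,
                                  conservation_bins = conservation_bins,
                                  min_len = min_helix_len, min_loop = min_loop,
                                  realign_cmd = realign_cmd)
  helices$p_value <- empirical_pvalue(helices$score, null)
  new_transat_fit(sort_predictions(helices), null, config, aln, tree)
}

new_transat_fit <- function(predictions, null, config, aln, tree) {
  structure(list(predictions = predictions, null = null, config = config,
                 alignment = aln, tree = tree),
            class = "transat_fit")
}

# ranking used everywhere: ascending p, then descending score, then
# lexicographic column-pair string
sort_predictions <- function(predictions) {
  key <- vapply(predictions$pairs,
                function(m) paste(sprintf("%06d:%06d", m[, 1], m[, 2]),
                                  collapse = ","), character(1))
  ord <- order(predictions$p_value, -predictions$score, key)
  predictions <- predictions[ord, ]
  predictions$helix <- seq_len(nrow(predictions))
  predictions
}

#' @export
print.transat_fit <- function(x, ...) {
  cat("Conserved-helix scan:", nrow(x$predictions), "helices on a",
      x$alignment$n_rows, "x", x$alignment$n_cols, "alignment\n")
  if (!is.null(x$null)) {
    cat("null:", x$null$n_scores, "scores from", x$null$n_shuffles,
        "shuffles;", sum(x$predictions$p_value <= 0.05),
        "helices with p <= 0.05\n")
  }
  invisible(x)
}

#' Per-helix results of a conserved-helix scan
#'
#' @param x A `transat_fit`.
#' @param ... Unused.
#' @return Tibble with one row per conserved helix: `helix`, `length`,
#'   `support`, the `pairs` list-column of column-pair matrices, `score` and
#'   `p_value`, ranked by ascending p-value.
#' @export
tidy.transat_fit <- function(x, ...) {
  x$predictions
}

#' One-row summary of a conserved-helix scan
#'
#' @param x A `transat_fit`.
#' @param ... Unused.
#' @return One-row tibble: helix counts, significant counts at p <= 0.05,
#'   null size and the seed used.
#' @export
glance.transat_fit <- function(x, ...) {
  tibble(
    n_helices = nrow(x$predictions),
    n_significant_05 = if (nrow(x$predictions))
      sum(x$predictions$p_value <= 0.05) else 0L,
    min_p = if (nrow(x$predictions)) min(x$predictions$p_value) else NA_real_,
    null_size = if (!is.null(x$null)) x$null$n_scores else 0L,
    shuffles = x$config$shuffles,
    seed = if (is.null(x$config$seed)) NA_integer_ else x$config$seed,
    total_tree_length = x$config$total_tree_length
  )
}

#' Arc diagram of a fit
#'
#' @param object A `transat_fit`.
#' @param reference Optional `rna_structure`; when absent and the alignment
#'   carried an `SS_cons` annotation, that is used; otherwise all significant
#'   pairs are drawn as novel.
#' @param p_hat P-value threshold for display (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transat_fit <- function(object, reference = NULL, p_hat = 0.05, ...) {
  if (is.null(reference)) {
    reference <- if (!is.null(object$alignment$ss_cons)) {
      parse_structure(object$alignment$ss_cons, object$alignment$n_cols)
    } else {
      rna_structure(integer(), integer(), object$alignment$n_cols)
    }
  }
  autoplot(arc_data(object$predictions, reference, p_hat))
}

#' Write scored predictions as TSV
#'
#' One row per helix: id, length in pairs, 1-based inclusive 5' and 3'
#' column ranges, the explicit comma-separated column pairs, log-likelihood
#' score, p-value and supporting-sequence count; ranked by ascending
#' p-value, ties broken by descending score then lexicographic pairs. Header
#' comment lines record the run configuration.
#'
#' @param x A `transat_fit` or a scored predictions tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(x, path) {
  header <- character()
  if (inherits(x, "transat_fit")) {
    cfg <- x$config
    header <- c(
      paste0("# transat ", as.character(utils::packageVersion("transat"))),
      paste0("# min_helix_len=", cfg$min_helix_len, " min_loop=", cfg$min_loop,
             " shuffles=", cfg$shuffles, " seed=",
             if (is.null(cfg$seed)) "NA" else cfg$seed,
             " conservation_bins=", cfg$conservation_bins))
    x <- x$predictions
  }
  if (nrow(x) && (is.null(x$score) || is.null(x$p_value) ||
                  anyNA(x$score) || anyNA(x$p_value))) {
    stop("predictions must be scored (score and p_value present) before ",
         "writing", call. = FALSE)
  }
  x <- if (nrow(x)) sort_predictions(x) else x
  rows <- tibble(
    helix = x$helix,
    length = x$length,
    col5 = vapply(x$pairs, function(m) paste0(min(m[, 1]), "-", max(m[, 1])),
                  character(1)),
    col3 = vapply(x$pairs, function(m) paste0(min(m[, 2]), "-", max(m[, 2])),
                  character(1)),
    pairs = vapply(x$pairs, function(m) paste(pair_keys(m[, 1], m[, 2]),
                                              collapse = ","), character(1)),
    score = x$score,
    p_value = x$p_value,
    support = x$support
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  writeLines(paste(names(rows), collapse = "\t"), con)
  if (nrow(rows)) {
    writeLines(do.call(paste, c(lapply(rows, format_tsv_col), sep = "\t")),
               con)
  }
  invisible(path)
}

format_tsv_col <- function(v) {
  if (is.numeric(v) && !is.integer(v)) format(v, digits = 10) else as.character(v)
}
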