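#' Minimum p-value per predicted base pair
#'
#' A base pair inherits its significance from the most significant predicted
#' helix containing it.
#'
#' @param predictions Scored predictions tibble (with `pairs` list-column and
#'   `p_value`), e.g. from [tidy()] of a fit.
#' @return Tibble with columns `i`, `j`, `min_p`, one row per distinct
#'   predicted column pair.
#' @export
basepair_min_pvalue <- function(predictions) {
  if (!nrow(predictions)) return(tibble(i = integer(), j = integer(),
                                        min_p = numeric()))
  if (is.null(predictions$p_value) || anyNA(predictions$p_value)) {
    stop("predictions must carry p-values", call. = FALSE)
  }
  long <- purrr::map2_dfr(predictions$pairs, predictions$p_value,
                          function(m, p) tibble(i = m[, 1], j = m[, 2], p = p))
  long |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(min_p = min(.data$p), .groups = "drop")
}

new_confusion <- function(tp, fp, tn, fn) {
  tibble(tp = as.integer(tp), fp = as.integer(fp),
         tn = as.integer(tn), fn = as.integer(fn))
}

#' Base-pair-level confusion counts at a p-value threshold
#'
#' A predicted pair is significant when its minimum p-value is at most
#' `p_hat`. Known pairs that are significant are TP; significant pairs
#' outside the reference are FP; known pairs that are insignificant *or never
#' predicted* are FN; predicted-but-insignificant pairs outside the reference
#' are TN. The evaluation universe is thus the union of known and predicted
#' pairs, not all O(n^2) column pairs -- the reported FPR depends on this
#' choice.
#'
#' @param predictions Scored predictions tibble.
#' @param reference An `rna_structure`.
#' @param p_hat P-value threshold.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
classify_basepairs <- function(predictions, reference, p_hat) {
  minp <- basepair_min_pvalue(predictions)
  pred_keys <- pair_keys(minp$i, minp$j)
  sig <- minp$min_p <= p_hat
  known_keys <- pair_keys(reference$i, reference$j)
  known_pred <- pred_keys %in% known_keys
  new_confusion(
    tp = sum(sig & known_pred),
    fp = sum(sig & !known_pred),
    tn = sum(!sig & !known_pred),
    fn = sum(!sig & known_pred) + sum(!(known_keys %in% pred_keys))
  )
}

#' Helix-level confusion counts at a p-value threshold
#'
#' A predicted helix *matches* the reference when at least `match_fraction`
#' of its column pairs are identical to reference pairs (ties at exactly the
#' fraction count as matching). Matching helices are TP when significant and
#' FN otherwise; non-matching helices are FP when significant and TN
#' otherwise.
#'
#' @param predictions Scored predictions tibble.
#' @param reference An `rna_structure`.
#' @param p_hat P-value threshold.
#' @param match_fraction Minimum fraction of matching pairs (default 0.7).
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
classify_helices <- function(predictions, reference, p_hat,
                             match_fraction = 0.7) {
  if (!nrow(predictions)) return(new_confusion(0, 0, 0, 0))
  known_keys <- pair_keys(reference$i, reference$j)
  frac <- vapply(predictions$pairs, function(m) {
    mean(pair_keys(m[, 1], m[, 2]) %in% known_keys)
  }, numeric(1))
  matches <- frac >= match_fraction
  sig <- predictions$p_value <= p_hat
  new_confusion(tp = sum(matches & sig), fp = sum(!matches & sig),
                tn = sum(!matches & !sig), fn = sum(matches & !sig))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, false positive rate `FP/(FP+TN)`, positive
#' predictive value `TP/(TP+FP)`, F-measure (harmonic mean of sensitivity
#' and PPV) and Matthews correlation coefficient. Any 0/0 is reported as
#' `NA` (undefined), never silently as 0.
#'
#' @param counts Tibble with columns `tp`, `fp`, `tn`, `fn` (one or more
#'   rows).
#' @return `counts` with columns `sens`, `fpr`, `ppv`, `f_measure`, `mcc`
#'   appended.
#' @export
compute_metrics <- function(counts) {
  for (col in c("tp", "fp", "tn", "fn")) {
    counts[[col]] <- as.numeric(counts[[col]])  # avoid integer overflow in MCC
  }
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  sens <- ratio(counts$tp, counts$tp + counts$fn)
  fpr <- ratio(counts$fp, counts$fp + counts$tn)
  ppv <- ratio(counts$tp, counts$tp + counts$fp)
  f <- ifelse(!is.na(sens) & !is.na(ppv) & (sens + ppv) > 0,
              2 * sens * ppv / (sens + ppv), NA_real_)
  mcc_den <- sqrt((counts$tp + counts$fp) * (counts$tp + counts$fn) *
                  (counts$tn + counts$fp) * (counts$tn + counts$fn))
  mcc <- ifelse(mcc_den > 0,
                (counts$tp * counts$tn - counts$fp * counts$fn) / mcc_den,
                NA_real_)
  dplyr::mutate(counts, sens = sens, fpr = fpr, ppv = ppv,
                f_measure = f, mcc = mcc)
}

#' Metrics across a grid of p-value thresholds
#'
#' Computes base-pair- and helix-level metrics at each threshold. With
#' multiple alignments (lists of predictions and references), per-alignment
#' metrics are macro-averaged; undefined (`NA`) entries are excluded from
#' each mean and the number of contributing alignments is reported per
#' metric.
#'
#' @param predictions A scored predictions tibble, or a list of them.
#' @param reference An `rna_structure`, or a list of them (parallel to
#'   `predictions`).
#' @param thresholds Ascending numeric vector of p-value thresholds.
#' @param match_fraction Helix match fraction (default 0.7).
#' @return Tibble with columns `threshold`, `level` (`"basepair"` or
#'   `"helix"`), the five metrics, and `n_defined_*` counts.
#' @export
threshold_sweep <- function(predictions, reference, thresholds,
                            match_fraction = 0.7) {
  if (is.data.frame(predictions)) predictions <- list(predictions)
  if (inherits(reference, "rna_structure")) reference <- list(reference)
  stopifnot(length(predictions) == length(reference),
            !is.unsorted(thresholds))
  metric_names <- c("sens", "fpr", "ppv", "f_measure", "mcc")
  grid <- tidyr::expand_grid(threshold = thresholds,
                             level = c("basepair", "helix"))
  purrr::pmap_dfr(grid, function(threshold, level) {
    per_aln <- purrr::map2_dfr(predictions, reference, function(p, r) {
      counts <- if (level == "basepair") {
        classify_basepairs(p, r, threshold)
      } else {
        classify_helices(p, r, threshold, match_fraction)
      }
      compute_metrics(counts)
    })
    means <- vapply(metric_names, function(m) mean(per_aln[[m]], na.rm = TRUE),
                    numeric(1))
    means[is.nan(means)] <- NA_real_
    ns <- vapply(metric_names, function(m) sum(!is.na(per_aln[[m]])),
                 numeric(1))
    tibble(threshold = threshold, level = level, !!!means,
           !!!setNames(ns, paste0("n_defined_", metric_names)))
  })
}

#' Alignment-quality statistics with respect to a reference structure
#'
#' `canonical_fraction` is the proportion of (row, reference-pair) cells
#' whose two characters form a consensus pair, with cells containing a gap
#' excluded from numerator and denominator. `covariation` is the fraction of
#' reference pairs at which at least two distinct consensus pair types occur
#' across the rows, i.e. pairs supported by compensatory substitutions.
#'
#' @param aln An `rna_alignment`.
#' @param reference A nonempty `rna_structure`.
#' @return One-row tibble with `canonical_fraction` and `covariation`.
#' @export
alignment_quality <- function(aln, reference) {
  if (!nrow(reference)) stop("reference structure is empty", call. = FALSE)
  mat <- alignment_matrix(aln)
  stats <- purrr::map2(reference$i, reference$j, function(i, j) {
    x <- mat[, i]; y <- mat[, j]
    keep <- x != "-" & y != "-"
    xi <- match(x[keep], NUCS); yi <- match(y[keep], NUCS)
    canon <- !is.na(xi) & !is.na(yi) & CONSENSUS_LOOKUP[cbind(
      ifelse(is.na(xi), 1L, xi), ifelse(is.na(yi), 1L, yi))]
    types <- unique(paste0(x[keep][canon], y[keep][canon]))
    list(n_cells = sum(keep), n_canon = sum(canon),
         covarying = length(types) >= 2)
  })
  tibble(
    canonical_fraction = sum(purrr::map_dbl(stats, "n_canon")) /
      sum(purrr::map_dbl(stats, "n_cells")),
    covariation = mean(purrr::map_lgl(stats, "covarying"))
  )
}

#' Arc-diagram data for predictions against a reference
#'
#' One row per arc: reference pairs are drawn above the axis, novel
#' significant pairs below. Significant pairs are binned into classes at
#' p-value cutoffs 1e-3, 1e-2 and `p_hat`; novel pairs above `p_hat` are
#' omitted; reference pairs that are never predicted at `p_hat` get class
#' `"known_only"`.
#'
#' @param predictions Scored predictions tibble.
#' @param reference An `rna_structure` (may be empty via
#'   `rna_structure(integer(), integer(), n)`).
#' @param p_hat P-value threshold (default 0.05).
#' @return Tibble with columns `i`, `j`, `side`, `min_p`, `class`.
#' @export
arc_data <- function(predictions, reference, p_hat = 0.05) {
  minp <- basepair_min_pvalue(predictions)
  known_keys <- pair_keys(reference$i, reference$j)
  pred_keys <- pair_keys(minp$i, minp$j)
  cls <- function(p) {
    dplyr::case_when(p <= 1e-3 ~ "p<=1e-3",
                     p <= 1e-2 ~ "p<=1e-2",
                     p <= p_hat ~ "p<=p_hat",
                     TRUE ~ NA_character_)
  }
  sig <- minp[minp$min_p <= p_hat, ]
  sig_keys <- pair_keys(sig$i, sig$j)
  above <- dplyr::mutate(sig[sig_keys %in% known_keys, ],
                         side = "above", class = cls(.data$min_p))
  below <- dplyr::mutate(sig[!(sig_keys %in% known_keys), ],
                         side = "below", class = cls(.data$min_p))
  missed <- reference[!(known_keys %in% sig_keys), c("i", "j")]
  missed <- dplyr::mutate(as_tibble(missed),
                          min_p = minp$min_p[match(pair_keys(.data$i, .data$j),
                                                   pred_keys)],
                          side = "above", class = "known_only")
  out <- dplyr::bind_rows(above, below, missed)
  out <- out[order(out$i, out$j), c("i", "j", "side", "min_p", "class")]
  class(out) <- c("transat_arcs", class(out))
  out
}

#' Write arc data to a TSV file
#'
#' @param arcs Tibble from [arc_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arc_data <- function(arcs, path) {
  write.table(arcs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Arc-diagram plot of predicted and known base pairs
#'
#' Known base pairs arc above the horizontal axis (black when detected by no
#' significant helix), novel significant pairs arc below; colour encodes the
#' minimum p-value class.
#'
#' @param object A `transat_arcs` tibble from [arc_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transat_arcs <- function(object, ...) {
  if (!nrow(object)) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  arcs <- purrr::pmap_dfr(
    list(object$i, object$j, object$side, object$class,
         seq_len(nrow(object))),
    function(i, j, side, class, id) {
      t <- seq(0, pi, length.out = 60)
      r <- (j - i) / 2
      tibble(x = (i + j) / 2 + r * cos(t),
             y = if (side == "above") r * sin(t) else -r * sin(t),
             class = class, arc = id)
    })
  cols <- c("p<=1e-3" = "#1b9e44", "p<=1e-2" = "#2c62b0",
            "p<=p_hat" = "#e08214", known_only = "black")
  ggplot2::ggplot(arcs, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$arc,
                                     colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = cols, name = "min p-value") +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
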