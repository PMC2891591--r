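# tiny constructor for scored prediction tibbles
make_pred <- function(pairs_list, p) {
  tibble::tibble(helix = seq_along(pairs_list),
                 length = vapply(pairs_list, nrow, integer(1)),
                 pairs = pairs_list, score = rev(seq_along(pairs_list)),
                 p_value = p,
                 support = 1L)
}

test_that("a base pair inherits the smallest p-value over its helices", {
  pred <- make_pred(list(cbind(i = c(1L, 2L), j = c(20L, 19L)),
                         cbind(i = c(2L, 3L), j = c(19L, 18L))),
                    p = c(0.2, 0.01))
  mp <- basepair_min_pvalue(pred)
  expect_equal(nrow(mp), 3)
  expect_equal(mp$min_p[mp$i == 1], 0.2)
  expect_equal(mp$min_p[mp$i == 2], 0.01)  # min over the two helices
  expect_equal(mp$min_p[mp$i == 3], 0.01)
  expect_error(basepair_min_pvalue(make_pred(list(cbind(1L, 5L)), NA_real_)),
               "p-values")
  expect_equal(nrow(basepair_min_pvalue(pred[0, ])), 0)
})

test_that("base-pair confusion uses the union of known and predicted pairs", {
  known <- rna_structure(c(1L, 2L, 3L, 4L), c(20L, 19L, 18L, 17L), 50L)
  pred <- make_pred(
    list(cbind(i = 1:3, j = 20:18),         # 3 known pairs, significant
         cbind(i = 5L, j = 16L),            # novel, significant
         cbind(i = 30:34, j = 40:36)),      # 5 novel, insignificant
    p = c(0.01, 0.02, 0.5))
  cm <- classify_basepairs(pred, known, p_hat = 0.05)
  expect_equal(cm$tp, 3L)
  expect_equal(cm$fp, 1L)
  expect_equal(cm$fn, 1L)  # (4,17) was never predicted
  expect_equal(cm$tn, 5L)
  # with no predictions every known pair is a miss
  cm0 <- classify_basepairs(pred[0, ], known, 0.05)
  expect_equal(unlist(cm0), c(tp = 0L, fp = 0L, tn = 0L, fn = 4L))
})

test_that("helix confusion applies the 70 percent match rule", {
  known <- rna_structure(1:20, 61:80, 100L)
  key_pairs <- cbind(i = 1:20, j = 61:80)
  pred <- make_pred(
    list(rbind(key_pairs[1:7, ], cbind(i = 31:33, j = 45:43)),    # 7/10
         rbind(key_pairs[8:16, ], cbind(i = 34:37, j = 52:49)),   # 9/13
         cbind(i = 21:24, j = 58:55),                             # 0 match
         key_pairs[17:20, ]),                                     # 4/4
    p = c(0.01, 0.01, 0.4, 0.4))
  cm <- classify_helices(pred, known, p_hat = 0.05)
  expect_equal(cm$tp, 1L)  # 7/10 = 0.7 counts as matching (ties match)
  expect_equal(cm$fp, 1L)  # 9/13 ~ 0.692 < 0.7
  expect_equal(cm$tn, 1L)
  expect_equal(cm$fn, 1L)  # perfect match but insignificant
  # a stricter fraction flips the tie
  cm2 <- classify_helices(pred, known, 0.05, match_fraction = 0.75)
  expect_equal(cm2$tp, 0L)
  expect_equal(cm2$fp, 2L)
  expect_equal(unlist(classify_helices(pred[0, ], known, 0.05)),
               c(tp = 0L, fp = 0L, tn = 0L, fn = 0L))
})

test_that("metric formulas match hand-computed values", {
  m <- compute_metrics(new_confusion(tp = 3, fp = 1, tn = 5, fn = 1))
  expect_equal(m$sens, 3 / 4)
  expect_equal(m$fpr, 1 / 6)
  expect_equal(m$ppv, 3 / 4)
  expect_equal(m$f_measure, 3 / 4)
  expect_equal(m$mcc, 14 / 24)
})

test_that("undefined metric ratios propagate as NA, never as 0", {
  m <- compute_metrics(new_confusion(tp = 0, fp = 0, tn = 4, fn = 2))
  expect_equal(m$sens, 0)
  expect_true(is.na(m$ppv))        # no positive predictions
  expect_true(is.na(m$f_measure))
  m2 <- compute_metrics(new_confusion(0, 0, 0, 0))
  expect_true(all(is.na(unlist(m2[, c("sens", "fpr", "ppv", "f_measure",
                                      "mcc")]))))
  # large counts do not overflow the MCC
  m3 <- compute_metrics(new_confusion(1e5, 1e5, 1e5, 1e5))
  expect_equal(m3$mcc, 0)
})

test_that("base-pair confusion matches a set-arithmetic oracle on random toys", {
  set.seed(61)
  for (rep in 1:40) {
    n <- 60L
    mk_pairs <- function(k) {
      i <- sample(1:25, k); j <- sample(35:60, k)
      cbind(i = as.integer(i), j = as.integer(j))
    }
    known_m <- unique(mk_pairs(sample(3:10, 1)))
    known <- rna_structure(known_m[, 1], known_m[, 2], n)
    nh <- sample(1:4, 1)
    pred <- make_pred(replicate(nh, mk_pairs(sample(2:8, 1)), simplify = FALSE),
                      p = runif(nh))
    p_hat <- runif(1)
    cm <- classify_basepairs(pred, known, p_hat)
    # oracle over explicit key sets
    mp <- basepair_min_pvalue(pred)
    P <- pair_keys(mp$i, mp$j)
    S <- P[mp$min_p <= p_hat]
    K <- pair_keys(known$i, known$j)
    expect_equal(cm$tp, length(intersect(S, K)))
    expect_equal(cm$fp, length(setdiff(S, K)))
    expect_equal(cm$tn, length(setdiff(setdiff(P, S), K)))
    expect_equal(cm$fn, length(setdiff(K, S)))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, length(union(P, K)))
  }
})

test_that("threshold sweep endpoints and monotonicity behave", {
  known <- rna_structure(c(1L, 2L, 3L, 4L), c(20L, 19L, 18L, 17L), 50L)
  pred <- make_pred(
    list(cbind(i = 1:4, j = 20:17), cbind(i = 6:9, j = 15:12)),
    p = c(0.004, 0.3))
  sw <- threshold_sweep(pred, known, thresholds = c(0.001, 0.05, 1))
  expect_equal(nrow(sw), 6)  # 3 thresholds x 2 levels
  bp <- sw[sw$level == "basepair", ]
  expect_equal(bp$sens, c(0, 1, 1))  # nondecreasing in threshold
  # at 0.001 nothing is significant: the 4 novel pairs are TN, so fpr = 0;
  # at 1 everything is significant, so the novel pairs all become FP
  expect_equal(bp$fpr, c(0, 0, 1))
  hx <- sw[sw$level == "helix", ]
  expect_equal(hx$sens, c(0, 1, 1))
  expect_true(all(sw$n_defined_sens == 1))
  expect_error(threshold_sweep(pred, known, c(0.5, 0.1)), "unsorted")
})

test_that("macro-averaging skips undefined per-alignment metrics", {
  known1 <- rna_structure(c(1L, 2L), c(12L, 11L), 20L)
  pred1 <- make_pred(list(cbind(i = 1:2, j = 12:11)), 0.01)
  # second alignment: nothing predicted -> ppv undefined there
  pred2 <- pred1[0, ]
  sw <- threshold_sweep(list(pred1, pred2), list(known1, known1), 0.05)
  bp <- sw[sw$level == "basepair", ]
  expect_equal(bp$ppv, 1)             # averaged over the defined alignment only
  expect_equal(bp$n_defined_ppv, 1)
  expect_equal(bp$sens, (1 + 0) / 2)  # defined in both (0 for the empty one)
  expect_equal(bp$n_defined_sens, 2)
})

test_that("alignment quality scores canonical fraction and covariation", {
  ref <- rna_structure(1L, 2L, 2L)
  expect_equal(alignment_quality(
    rna_alignment(c("a", "b"), c("GC", "AU")), ref)$canonical_fraction, 1)
  q <- alignment_quality(rna_alignment(c("a", "b"), c("GC", "GA")), ref)
  expect_equal(q$canonical_fraction, 0.5)
  expect_equal(q$covariation, 0)        # only one canonical type present
  q2 <- alignment_quality(rna_alignment(c("a", "b"), c("GC", "AU")), ref)
  expect_equal(q2$covariation, 1)       # two distinct canonical types
  # gapped cells are excluded from both numerator and denominator
  q3 <- alignment_quality(rna_alignment(c("a", "b", "c"),
                                        c("GC", "G-", "GA")), ref)
  expect_equal(q3$canonical_fraction, 0.5)
  # identical canonical pairs everywhere: conserved but not covarying
  q4 <- alignment_quality(rna_alignment(c("a", "b"), c("GC", "GC")), ref)
  expect_equal(q4$covariation, 0)
  expect_error(alignment_quality(rna_alignment("a", "GC"),
                                 rna_structure(integer(), integer(), 2L)),
               "empty")
})

test_that("arc data separates known, novel and missed pairs by class", {
  known <- rna_structure(c(1L, 2L, 3L), c(30L, 29L, 28L), 40L)
  pred <- make_pred(
    list(cbind(i = 1L, j = 30L),    # known, very significant
         cbind(i = 2L, j = 29L),    # known, marginal
         cbind(i = 10L, j = 22L),   # novel, significant
         cbind(i = 11L, j = 21L)),  # novel, insignificant -> omitted
    p = c(1e-4, 0.03, 0.008, 0.4))
  arcs <- arc_data(pred, known, p_hat = 0.05)
  expect_setequal(colnames(arcs), c("i", "j", "side", "min_p", "class"))
  row <- function(i) arcs[arcs$i == i, ]
  expect_equal(row(1)$class, "p<=1e-3")
  expect_equal(row(1)$side, "above")
  expect_equal(row(2)$class, "p<=p_hat")
  expect_equal(row(10)$class, "p<=1e-2")
  expect_equal(row(10)$side, "below")
  expect_false(11 %in% arcs$i)                  # insignificant novel omitted
  expect_equal(row(3)$class, "known_only")      # never predicted
  expect_true(is.na(row(3)$min_p))
  expect_equal(row(3)$side, "above")

  p <- ggplot2::ggplot_build(autoplot(arcs))    # renders without error
  expect_gt(nrow(p$data[[2]]), 0)
  f <- tempfile(fileext = ".tsv")
  write_arc_data(arcs, f)
  expect_equal(nrow(read.delim(f)), nrow(arcs))
})
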