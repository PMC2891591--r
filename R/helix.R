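#' Enumerate candidate helices in one ungapped sequence
#'
#' Scans a single ungapped RNA sequence for all maximal runs of consecutive
#' consensus base pairs (AU, UA, GC, CG, GU, UG). A run pairs positions
#' `(p + k, q - k)` for `k = 0 .. len - 1`; it is reported when it contains at
#' least `min_len` pairs, its innermost pair encloses at least `min_loop`
#' unpaired nucleotides, and it can be extended neither outward nor inward
#' (inward extension may be blocked by the loop constraint as well as by a
#' non-consensus pair). `N` never pairs, so a run is split around it.
#'
#' Implementation note: all pairs of one run share the same position sum
#' `p + q`, so runs are found as runs of consensus pairs along the
#' anti-diagonals of the pairing matrix.
#'
#' @param sequence Ungapped RNA sequence (string over `A,C,G,U,N`).
#' @param min_len Minimum number of consecutive pairs in a helix (default 4).
#' @param min_loop Minimum number of unpaired nucleotides enclosed by the
#'   innermost pair (default 3).
#' @return A tibble with one row per helix: `length`, and `pairs`, a
#'   list-column of `length x 2` integer matrices of 1-based sequence
#'   positions `(p, q)` with `p` ascending and `q` descending.
#' @export
enumerate_sequence_helices <- function(sequence, min_len = 4, min_loop = 3) {
  stopifnot(length(sequence) == 1, min_len >= 1, min_loop >= 0)
  chars <- strsplit(sequence, "")[[1]]
  if (any(chars == "-")) {
    stop("sequence contains gaps; helices are enumerated on ungapped sequences",
         call. = FALSE)
  }
  idx <- match(chars, NUCS)  # NA for N
  if (any(is.na(idx) & chars != "N")) {
    stop("invalid character in sequence", call. = FALSE)
  }
  n <- length(chars)
  empty <- tibble(length = integer(), pairs = list())
  if (n < 2 * min_len + min_loop) return(empty)

  # pairs (p, q) of one helix share d = p + q, so helices are runs of
  # consensus pairs along anti-diagonals. All diagonals are laid out in one
  # flat logical vector with FALSE separators, so a single rle finds every
  # run; the loop constraint bounds each diagonal at q - p >= min_loop + 1.
  ds <- seq(3L, 2L * n - 1L)
  p_lo <- pmax(1L, ds - n)
  p_hi <- (ds - min_loop - 1L) %/% 2L  # q - p >= min_loop + 1
  lens <- p_hi - p_lo + 1L
  keep_d <- lens >= 1L
  ds <- ds[keep_d]; p_lo <- p_lo[keep_d]; lens <- lens[keep_d]
  if (!length(ds)) return(empty)
  p_all <- sequence(lens) - 1L + rep(p_lo, lens)
  q_all <- rep(ds, lens) - p_all
  ok_all <- !is.na(idx[p_all]) & !is.na(idx[q_all])
  ok_all[ok_all] <- CONSENSUS_LOOKUP[cbind(idx[p_all[ok_all]],
                                           idx[q_all[ok_all]])]
  slots <- seq_along(p_all) + rep(seq_along(lens) - 1L, lens)
  V <- logical(length(p_all) + length(lens))
  V[slots] <- ok_all
  P <- integer(length(V)); P[slots] <- p_all
  D <- integer(length(V)); D[slots] <- rep(ds, lens)
  r <- rle(V)
  run_ends <- cumsum(r$lengths)
  sel <- r$values & r$lengths >= min_len
  if (!any(sel)) return(empty)
  run_starts <- (run_ends - r$lengths + 1L)[sel]
  run_lens <- r$lengths[sel]
  lengths_out <- run_lens
  pairs_out <- purrr::map2(run_starts, run_lens, function(v0, len) {
    p0 <- P[v0]
    cbind(p = p0:(p0 + len - 1L), q = D[v0] - (p0:(p0 + len - 1L)))
  })
  ord <- order(vapply(pairs_out, function(m) m[1, 1], integer(1)),
               lengths_out,
               vapply(pairs_out, function(m) m[1, 2], integer(1)))
  tibble(length = lengths_out[ord], pairs = pairs_out[ord])
}

#' Map ungapped-sequence helix positions to alignment columns
#'
#' Position `p` of the ungapped row maps to the alignment column holding the
#' `p`-th non-gap character of that row. The mapping is a bijection between
#' ungapped positions and the row's non-gap columns, so mapped pairs inherit
#' the helix order; mapped columns need not be adjacent.
#'
#' @param pairs `L x 2` matrix of ungapped positions from
#'   [enumerate_sequence_helices()].
#' @param aln An `rna_alignment`.
#' @param row Row index or id whose gap pattern defines the mapping.
#' @return `L x 2` integer matrix of alignment columns `(i, j)`.
#' @export
map_helix_to_alignment <- function(pairs, aln, row) {
  chars <- strsplit(aln$seqs[[row]], "")[[1]]
  colmap <- which(chars != "-")
  if (max(pairs) > length(colmap)) {
    stop("helix position beyond ungapped length of row", call. = FALSE)
  }
  m <- cbind(i = colmap[pairs[, 1]], j = colmap[pairs[, 2]])
  storage.mode(m) <- "integer"
  m
}

#' Collect conserved helices across all alignment rows
#'
#' Enumerates helices on every ungapped row, maps each onto alignment
#' columns, and merges helices whose column-pair lists are identical; the
#' number of contributing rows is recorded as `support`. Distinct (even
#' heavily overlapping) column-pair lists are kept as separate conserved
#' helices. Output order is deterministic: by first 5' column, then helix
#' length, then first 3' column.
#'
#' @param aln An `rna_alignment`.
#' @param min_len,min_loop Passed to [enumerate_sequence_helices()].
#' @return A tibble with columns `helix` (integer id), `length`, `support`,
#'   and the list-column `pairs` of `L x 2` alignment-column matrices.
#' @export
collect_conserved_helices <- function(aln, min_len = 4, min_loop = 3) {
  stopifnot(inherits(aln, "rna_alignment"))
  seen <- new.env(parent = emptyenv())
  store <- list()
  support <- integer()
  for (r in seq_len(aln$n_rows)) {
    hs <- enumerate_sequence_helices(ungapped_row(aln, r), min_len, min_loop)
    if (!nrow(hs)) next
    for (pr in hs$pairs) {
      mapped <- map_helix_to_alignment(pr, aln, r)
      key <- paste(mapped, collapse = ",")
      hit <- seen[[key]]
      if (is.null(hit)) {
        store[[length(store) + 1L]] <- mapped
        support <- c(support, 1L)
        seen[[key]] <- length(store)
      } else {
        support[hit] <- support[hit] + 1L
      }
    }
  }
  if (!length(store)) {
    return(tibble(helix = integer(), length = integer(),
                  support = integer(), pairs = list()))
  }
  lens <- vapply(store, nrow, integer(1))
  ord <- order(vapply(store, function(m) m[1, 1], integer(1)),
               lens,
               vapply(store, function(m) m[1, 2], integer(1)))
  tibble(helix = seq_along(ord), length = lens[ord],
         support = support[ord], pairs = store[ord])
}
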