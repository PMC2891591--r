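#' Parse a dot-bracket / WUSS secondary structure string
#'
#' Supports the bracket tiers `()`, `<>`, `[]`, `{}`, `Aa` and `Bb`, so
#' pseudoknotted (crossing) structures are representable. All of
#' `. , : _ - ~` denote unpaired columns. Brackets are matched per tier with
#' a stack, so crossing pairs between tiers are kept.
#'
#' @param string Structure string, one character per alignment column.
#' @param n_cols Expected number of columns; defaults to `nchar(string)`.
#' @return An `rna_structure`: a tibble with integer columns `i < j`
#'   (1-based alignment columns) sorted by `i`, with attribute `n_cols`.
#' @export
parse_structure <- function(string, n_cols = nchar(string)) {
  if (nchar(string) != n_cols) {
    stop("structure string has ", nchar(string), " characters, expected ",
         n_cols, call. = FALSE)
  }
  chars <- strsplit(string, "")[[1]]
  open <- c("(", "<", "[", "{", "A", "B")
  close <- c(")", ">", "]", "}", "a", "b")
  unpaired <- c(".", ",", ":", "_", "-", "~")
  stacks <- rep(list(integer()), length(open))
  ii <- integer(); jj <- integer()
  for (k in seq_along(chars)) {
    ch <- chars[k]
    t_open <- match(ch, open)
    t_close <- match(ch, close)
    if (!is.na(t_open)) {
      stacks[[t_open]] <- c(stacks[[t_open]], k)
    } else if (!is.na(t_close)) {
      st <- stacks[[t_close]]
      if (length(st) == 0) {
        stop("unbalanced structure string: unmatched '", ch, "' at column ", k,
             call. = FALSE)
      }
      ii <- c(ii, st[length(st)]); jj <- c(jj, k)
      stacks[[t_close]] <- st[-length(st)]
    } else if (!(ch %in% unpaired)) {
      stop("unsupported structure character '", ch, "' at column ", k,
           call. = FALSE)
    }
  }
  leftover <- which(lengths(stacks) > 0)
  if (length(leftover)) {
    stop("unbalanced structure string: unmatched '",
         paste(open[leftover], collapse = "' '"), "'", call. = FALSE)
  }
  rna_structure(ii, jj, n_cols)
}

#' Construct a reference structure from explicit pairs
#'
#' @param i,j Integer vectors of paired 1-based columns, `i < j` enforced by
#'   swapping where needed.
#' @param n_cols Number of alignment columns the structure spans.
#' @return An `rna_structure` tibble.
#' @export
rna_structure <- function(i, j, n_cols) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j))
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo == hi)) stop("a column cannot pair with itself", call. = FALSE)
  if (length(lo) && (min(lo) < 1 || max(hi) > n_cols)) {
    stop("pair index outside 1..n_cols", call. = FALSE)
  }
  if (anyDuplicated(c(lo, hi))) {
    stop("a column appears in more than one base pair", call. = FALSE)
  }
  out <- tibble(i = lo, j = hi)
  out <- out[order(out$i), ]
  attr(out, "n_cols") <- as.integer(n_cols)
  class(out) <- c("rna_structure", class(out))
  out
}

#' Render a structure as a dot-bracket string
#'
#' Pairs are assigned greedily to the first bracket tier in which they nest
#' without crossing, so pseudoknots spill into `<>`, `[]`, `{}`, `Aa`, `Bb`.
#'
#' @param structure An `rna_structure`.
#' @return Dot-bracket string of length `n_cols`.
#' @export
structure_to_string <- function(structure) {
  n <- attr(structure, "n_cols")
  open <- c("(", "<", "[", "{", "A", "B")
  close <- c(")", ">", "]", "}", "a", "b")
  out <- rep(".", n)
  tiers <- list()
  ord <- order(structure$i)
  for (k in ord) {
    i <- structure$i[k]; j <- structure$j[k]
    placed <- FALSE
    for (t in seq_along(open)) {
      existing <- tiers[[as.character(t)]]
      crossing <- !is.null(existing) &&
        any((existing$i < i & i < existing$j & existing$j < j) |
            (i < existing$i & existing$i < j & j < existing$j))
      if (!crossing) {
        tiers[[as.character(t)]] <- rbind(existing, data.frame(i = i, j = j))
        out[i] <- open[t]; out[j] <- close[t]
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("structure too deeply pseudoknotted for 6 bracket tiers",
                      call. = FALSE)
  }
  paste(out, collapse = "")
}

# canonical "i:j" keys for sets of pairs
pair_keys <- function(i, j) paste(i, j, sep = ":")
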