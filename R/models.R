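#' Load the default unpaired and paired substitution models
#'
#' Reads the 4-state single-nucleotide and 16-state dinucleotide reversible
#' rate models shipped with the package (plain-text files under
#' `extdata/models/`; these are constructed models, see the file headers and
#' the methods vignette). A directory of user-supplied model files can be
#' given instead; it must contain one file matching `unpaired*.txt` and one
#' matching `paired*.txt` in the same format.
#'
#' @param model_dir Optional directory with replacement model files.
#' @return A list with elements `unpaired` and `paired`, each an `evo_model`.
#' @export
load_default_models <- function(model_dir = NULL) {
  if (is.null(model_dir)) {
    model_dir <- system.file("extdata", "models", package = "transat")
  }
  find1 <- function(pat) {
    f <- list.files(model_dir, pattern = pat, full.names = TRUE)
    if (length(f) != 1) {
      stop("expected exactly one model file matching '", pat, "' in ",
           model_dir, call. = FALSE)
    }
    f
  }
  list(unpaired = read_model_file(find1("^unpaired.*\\.txt$")),
       paired = read_model_file(find1("^paired.*\\.txt$")))
}

#' Read a reversible rate-model file
#'
#' The format is whitespace-delimited plain text: comment lines starting with
#' `#`, a `states` line naming the state order, a `pi` line with the
#' equilibrium frequencies, a line `Q`, and then the rate matrix rows. The
#' loader renormalises `pi` to sum to one and validates that `Q` has
#' non-negative off-diagonals, zero row sums, and satisfies detailed balance
#' `pi_a Q[a,b] = pi_b Q[b,a]` to 1e-9.
#'
#' @param path Model file path.
#' @return An `evo_model`: list with `states`, `nstate`, `pi`, `Q` and a
#'   cached spectral decomposition used by [transition_matrix()].
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fail <- function(msg) stop("malformed model file ", path, ": ", msg,
                             call. = FALSE)
  s_line <- grep("^states\\s", lines, value = TRUE)
  p_line <- grep("^pi\\s", lines, value = TRUE)
  q_at <- which(trimws(lines) == "Q")
  if (length(s_line) != 1 || length(p_line) != 1 || length(q_at) != 1) {
    fail("need exactly one 'states' line, one 'pi' line and one 'Q' marker")
  }
  states <- strsplit(trimws(sub("^states", "", s_line)), "\\s+")[[1]]
  k <- length(states)
  pi <- suppressWarnings(as.numeric(
    strsplit(trimws(sub("^pi", "", p_line)), "\\s+")[[1]]))
  if (length(pi) != k || anyNA(pi) || any(pi <= 0)) fail("bad pi line")
  if (length(lines) < q_at + k) fail("too few Q rows")
  Q <- t(vapply(lines[(q_at + 1):(q_at + k)], function(x) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(x), "\\s+")[[1]]))
    if (length(v) != k || anyNA(v)) fail("bad Q row")
    v
  }, numeric(k), USE.NAMES = FALSE))
  pi <- pi / sum(pi)
  evo_model(states, pi, Q)
}

#' Construct (and validate) a reversible evolutionary model
#'
#' @param states Character vector naming the states, in matrix order.
#' @param pi Equilibrium frequencies (renormalised to sum 1).
#' @param Q Rate matrix: off-diagonals non-negative, rows summing to zero,
#'   reversible with respect to `pi`.
#' @return An `evo_model` object.
#' @export
evo_model <- function(states, pi, Q) {
  k <- length(states)
  stopifnot(is.matrix(Q), nrow(Q) == k, ncol(Q) == k, length(pi) == k)
  pi <- pi / sum(pi)
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("negative off-diagonal rate", call. = FALSE)
  if (max(abs(rowSums(Q))) > 1e-8) {
    stop("rate-matrix rows do not sum to zero", call. = FALSE)
  }
  flux <- pi * Q  # flux[a, b] = pi_a Q[a, b]
  if (max(abs(flux - t(flux))) > 1e-9) {
    stop("rate matrix is not reversible with respect to pi ",
         "(detailed balance violated)", call. = FALSE)
  }
  # symmetrise: S = D Q D^-1 with D = diag(sqrt(pi)) has a real spectrum
  sq <- sqrt(pi)
  S <- sq * Q * rep(1 / sq, each = k)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  structure(
    list(states = states, nstate = k, pi = pi, Q = Q,
         A = (1 / sq) * e$vectors,          # P(t) = A diag(e^{lambda t}) B
         B = t(e$vectors * sq),
         lambda = e$values,
         cache = new.env(parent = emptyenv())),
    class = "evo_model"
  )
}

#' @export
print.evo_model <- function(x, ...) {
  cat("Reversible CTMC model:", x$nstate, "states (",
      paste(head(x$states, 4), collapse = ","),
      if (x$nstate > 4) ", ...", ")\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the cached spectral decomposition of the symmetrised rate
#' matrix; results are memoised per distinct `t`, which makes repeated
#' pruning over trees with few distinct branch lengths cheap. Tiny negative
#' entries from round-off are clipped to zero.
#'
#' @param model An `evo_model`.
#' @param t Non-negative evolutionary time (branch length).
#' @return A `nstate x nstate` stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "evo_model"))
  if (length(t) != 1 || is.na(t) || t < 0) {
    stop("branch length must be a single non-negative number", call. = FALSE)
  }
  key <- format(t, digits = 17)
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- model$A %*% (exp(model$lambda * t) * model$B)
  P[P < 0] <- 0
  dimnames(P) <- list(model$states, model$states)
  model$cache[[key]] <- P
  P
}

#' Felsenstein leaf vector for an unpaired column
#'
#' One-hot for an observed nucleotide; all-ones (missing information) for `N`
#' and for gaps.
#'
#' @param chars Character vector of observed symbols in `A,C,G,U,N,-`.
#' @return A `4 x length(chars)` numeric matrix of per-state indicators.
#' @export
leaf_vector_unpaired <- function(chars) {
  bad <- !(chars %in% c(NUCS, "N", "-"))
  if (any(bad)) stop("invalid symbol(s): ", paste(unique(chars[bad]),
                                                  collapse = ", "),
                     call. = FALSE)
  m <- matrix(0, nrow = 4, ncol = length(chars), dimnames = list(NUCS, NULL))
  obs <- match(chars, NUCS)
  m[cbind(obs[!is.na(obs)], which(!is.na(obs)))] <- 1
  m[, is.na(obs)] <- 1
  m
}

# index of dinucleotide state (x, y) in PAIR_STATES, bases as 1..4
pair_state_index <- function(xi, yi) 4L * (xi - 1L) + yi

# per-base masks over the 16 pair states used for one-sided gaps:
# states with the given first (second) base that are NOT consensus pairs
ONE_SIDED_MASKS <- local({
  canon_idx <- match(CONSENSUS_PAIRS, PAIR_STATES)
  first <- lapply(1:4, function(b) {
    v <- numeric(16); v[pair_state_index(b, 1:4)] <- 1; v[canon_idx] <- 0; v
  })
  second <- lapply(1:4, function(b) {
    v <- numeric(16); v[pair_state_index(1:4, b)] <- 1; v[canon_idx] <- 0; v
  })
  list(first = first, second = second)
})

#' Felsenstein leaf vector for a pair of base-paired columns
#'
#' Encodes the gap semantics of the paired model: two observed nucleotides
#' give a one-hot vector over the 16 dinucleotide states; a two-sided gap is
#' missing information (all ones, a helix may gain or lose whole base pairs
#' over time); a one-sided gap is a *non-consensus* observation -- an
#' indicator over the non-consensus states that share the observed base --
#' because half a base pair cannot be gained or lost. `N` behaves like a gap
#' on its side.
#'
#' @param x,y Character vectors (same length) of the symbols observed in the
#'   5' and 3' column respectively.
#' @return A `16 x length(x)` numeric matrix.
#' @export
leaf_vector_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- c(NUCS, "N", "-")
  bad <- !(x %in% ok) | !(y %in% ok)
  if (any(bad)) stop("invalid symbol(s) in paired columns", call. = FALSE)
  xi <- match(x, NUCS); yi <- match(y, NUCS)  # NA for N and '-'
  m <- matrix(0, nrow = 16, ncol = length(x),
              dimnames = list(PAIR_STATES, NULL))
  both <- !is.na(xi) & !is.na(yi)
  m[cbind(pair_state_index(xi[both], yi[both]), which(both))] <- 1
  neither <- is.na(xi) & is.na(yi)
  m[, neither] <- 1
  x_only <- !is.na(xi) & is.na(yi)
  for (k in which(x_only)) m[, k] <- ONE_SIDED_MASKS$first[[xi[k]]]
  y_only <- is.na(xi) & !is.na(yi)
  for (k in which(y_only)) m[, k] <- ONE_SIDED_MASKS$second[[yi[k]]]
  m
}
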