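#' Construct a validated RNA multiple alignment
#'
#' Builds the alignment container used throughout the package from row
#' identifiers and gapped sequences. Sequences are normalised: case-folded to
#' upper case, `T` converted to `U`, `.` converted to `-`, and IUPAC ambiguity
#' codes collapsed to `N` (treated as missing information downstream).
#'
#' @param ids Character vector of unique row identifiers.
#' @param seqs Character vector of gapped sequences, same length as `ids`.
#' @param ss_cons Optional consensus-structure annotation string (e.g. the
#'   `#=GC SS_cons` line of a Stockholm file), kept verbatim.
#' @return An object of class `rna_alignment`: a list with elements `ids`,
#'   `seqs` (named character vector), `n_rows`, `n_cols` and `ss_cons`.
#' @export
rna_alignment <- function(ids, seqs, ss_cons = NULL) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs)) {
    stop("`ids` and `seqs` must have the same length", call. = FALSE)
  }
  if (length(seqs) < 2) {
    stop("an alignment needs at least 2 sequences", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_rna(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  if (lens[1] == 0) stop("alignment has zero columns", call. = FALSE)
  bad <- grepl("[^ACGUN-]", seqs)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  if (any(gsub("-", "", seqs) == "")) {
    stop("all-gap row(s): ",
         paste(ids[gsub("-", "", seqs) == ""], collapse = ", "), call. = FALSE)
  }
  structure(
    list(ids = ids, seqs = setNames(seqs, ids),
         n_rows = length(ids), n_cols = lens[1], ss_cons = ss_cons),
    class = "rna_alignment"
  )
}

normalize_rna <- function(x) {
  x <- toupper(x)
  x <- chartr("T.", "U-", x)
  # IUPAC ambiguity codes carry partial information; we conservatively treat
  # them as fully missing
  gsub("[RYSWKMBDHV]", "N", x)
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("RNA alignment:", x$n_rows, "sequences x", x$n_cols, "columns\n")
  shown <- head(x$ids, 6)
  for (id in shown) {
    s <- x$seqs[[id]]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  %-15s %s\n", id, s))
  }
  if (x$n_rows > 6) cat("  ...\n")
  if (!is.null(x$ss_cons)) cat("  consensus structure annotation present\n")
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln An `rna_alignment`.
#' @return `n_rows x n_cols` character matrix with row names set to the ids.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "rna_alignment"))
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- aln$ids
  m
}

#' Read a multiple RNA sequence alignment
#'
#' Reads aligned FASTA, Clustal, or Stockholm. The format is auto-detected
#' from the file header unless given. For Stockholm input the `#=GC SS_cons`
#' annotation, when present, is retained and can be parsed with
#' [parse_structure()].
#'
#' @param path Path to the alignment file.
#' @param format One of `"auto"`, `"fasta"`, `"clustal"`, `"stockholm"`.
#' @return An [rna_alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- detect_alignment_format(path)
  switch(format,
    fasta = read_alignment_fasta(path),
    clustal = read_alignment_clustal(path),
    stockholm = read_alignment_stockholm(path)
  )
}

detect_alignment_format <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty alignment file: ", path, call. = FALSE)
  first <- lines[1]
  if (grepl("^# STOCKHOLM", first)) return("stockholm")
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) return("clustal")
  if (startsWith(first, ">")) return("fasta")
  stop("cannot detect alignment format of ", path, call. = FALSE)
}

read_alignment_fasta <- function(path) {
  # Biostrings handles the FASTA framing; normalization happens in the
  # constructor (inputs may legitimately contain T, lower case, or '.')
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  rna_alignment(ids, as.character(set))
}

read_alignment_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty Clustal file: ", path, call. = FALSE)
  if (!grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
    stop("not a Clustal file (missing CLUSTAL header): ", path, call. = FALSE)
  }
  body <- lines[-1]
  seqs <- list()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    # conservation lines contain only * : . and spaces
    if (grepl("^[\\s*:.]+$", ln, perl = TRUE)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)", ln))[[1]]
    if (length(m) < 3) next
    id <- m[2]; chunk <- gsub("[0-9]", "", m[3])
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], chunk)
  }
  if (length(seqs) == 0) stop("no sequences in Clustal file: ", path, call. = FALSE)
  rna_alignment(names(seqs), unlist(seqs))
}

read_alignment_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1])) {
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path,
         call. = FALSE)
  }
  seqs <- list()
  ss_chunks <- character()
  for (ln in lines[-1]) {
    if (ln == "//") break
    if (startsWith(ln, "#=GC SS_cons")) {
      ss_chunks <- c(ss_chunks, sub("^#=GC SS_cons\\s+", "", ln))
      next
    }
    if (startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)\\s*$", ln))[[1]]
    if (length(m) < 3) next
    seqs[[m[2]]] <- paste0(if (is.null(seqs[[m[2]]])) "" else seqs[[m[2]]], m[3])
  }
  if (length(seqs) == 0) stop("no sequences in Stockholm file: ", path, call. = FALSE)
  ss <- if (length(ss_chunks)) paste(ss_chunks, collapse = "") else NULL
  rna_alignment(names(seqs), unlist(seqs), ss_cons = ss)
}

#' Write an alignment to file
#'
#' @param aln An `rna_alignment`.
#' @param path Output file.
#' @param format `"fasta"`, `"clustal"` or `"stockholm"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal", "stockholm")) {
  stopifnot(inherits(aln, "rna_alignment"))
  format <- match.arg(format)
  out <- switch(format,
    fasta = as.vector(rbind(paste0(">", aln$ids), unname(aln$seqs))),
    clustal = {
      w <- max(nchar(aln$ids)) + 2
      c("CLUSTAL W multiple sequence alignment", "",
        sprintf(paste0("%-", w, "s%s"), aln$ids, unname(aln$seqs)))
    },
    stockholm = {
      w <- max(nchar(aln$ids), nchar("#=GC SS_cons")) + 2
      body <- sprintf(paste0("%-", w, "s%s"), aln$ids, unname(aln$seqs))
      ss <- if (!is.null(aln$ss_cons)) {
        sprintf(paste0("%-", w, "s%s"), "#=GC SS_cons", aln$ss_cons)
      }
      c("# STOCKHOLM 1.0", body, ss, "//")
    }
  )
  writeLines(out, path)
  invisible(path)
}

#' Remove gaps from one alignment row
#'
#' @param aln An `rna_alignment`.
#' @param row Row index or id.
#' @return Ungapped sequence string.
#' @export
ungapped_row <- function(aln, row) {
  gsub("-", "", aln$seqs[[row]])
}

#' Verify that tree leaves and alignment rows match
#'
#' Succeeds iff the tree tip labels and the alignment row ids are equal as
#' sets (order is irrelevant).
#'
#' @param aln An `rna_alignment`.
#' @param tree A rooted `phylo` tree.
#' @return A tibble with columns `row_id` and `tip` (tip number in the tree),
#'   one row per sequence.
#' @export
match_leaves <- function(aln, tree) {
  stopifnot(inherits(aln, "rna_alignment"), inherits(tree, "phylo"))
  only_aln <- setdiff(aln$ids, tree$tip.label)
  only_tree <- setdiff(tree$tip.label, aln$ids)
  if (length(only_aln) || length(only_tree)) {
    stop("alignment rows and tree leaves do not match",
         if (length(only_aln)) paste0("; only in alignment: ",
                                      paste(only_aln, collapse = ", ")),
         if (length(only_tree)) paste0("; only in tree: ",
                                       paste(only_tree, collapse = ", ")),
         call. = FALSE)
  }
  tibble(row_id = aln$ids, tip = match(aln$ids, tree$tip.label))
}
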