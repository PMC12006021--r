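#' Protein alignment scoring scheme
#'
#' Bundles a residue substitution matrix, affine gap penalties and
#' Karlin-Altschul statistical parameters. A gap of length \eqn{g} costs
#' \eqn{open + extend (g - 1)}. The default matrix is BLOSUM62 (taken from
#' \pkg{Biostrings}) restricted to the 20 standard residues plus X, with the
#' X row and column set to 0 so that unknown residues neither reward nor
#' penalise an alignment. The default Karlin-Altschul parameters
#' (\eqn{\lambda = 0.267}, \eqn{K = 0.041}) are the standard gapped values
#' for BLOSUM62 with gap open 11 / extend 1.
#'
#' @param substitution_matrix square numeric matrix with residue row/column
#'   names covering at least the 20 standard amino acids. `NULL` (default)
#'   uses BLOSUM62 with a zeroed X row/column.
#' @param gap_open positive penalty for the first column of a gap.
#' @param gap_extend positive penalty for each further column; must not
#'   exceed `gap_open`.
#' @param ka_lambda,ka_K positive Karlin-Altschul parameters used by
#'   [evalue()].
#' @return An object of class `"scoring_scheme"`.
#' @examples
#' sc <- scoring_scheme()
#' sc$substitution_matrix["A", "A"]
#' @export
scoring_scheme <- function(substitution_matrix = NULL, gap_open = 11,
                           gap_extend = 1, ka_lambda = 0.267, ka_K = 0.041) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_matrix()
  m <- substitution_matrix
  if (!is.matrix(m) || nrow(m) != ncol(m) || is.null(rownames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop("substitution_matrix must be square with matching row/column names")
  if (!all(AA20 %in% rownames(m)))
    stop("substitution_matrix must cover the 20 standard amino acids")
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution_matrix must be symmetric")
  if (!"X" %in% rownames(m)) {
    m <- rbind(cbind(m, X = 0), X = 0)
    rownames(m)[nrow(m)] <- "X"
  }
  m <- m[AA21, AA21]
  if (!(gap_open > 0 && gap_extend > 0))
    stop("gap penalties must be positive")
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open")
  if (!(ka_lambda > 0 && ka_K > 0))
    stop("ka_lambda and ka_K must be positive")
  structure(list(substitution_matrix = m, gap_open = gap_open,
                 gap_extend = gap_extend, ka_lambda = ka_lambda,
                 ka_K = ka_K),
            class = "scoring_scheme")
}

# BLOSUM62 restricted to 20 residues + X, X scored 0 against everything
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  m <- rbind(cbind(m, X = 0), X = 0)
  rownames(m)[nrow(m)] <- "X"
  storage.mode(m) <- "double"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix layout used by BLAST (`#` comment lines, a
#' header row of residue letters, one labelled row per residue).
#'
#' @param path path to the matrix file.
#' @return A symmetric numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path)
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  lab <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) as.numeric(r[-1L]))
  if (any(lengths(vals) != length(cols)))
    stop("matrix rows do not match header length")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(lab, cols)
  m
}

#' Write a substitution matrix in NCBI text format
#' @param m numeric matrix with residue dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(m, path) {
  hdr <- paste(colnames(m), collapse = "  ")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(rownames(m)[i], paste(m[i, ], collapse = "  ")), "")
  writeLines(c(paste(" ", hdr), body), path)
  invisible(path)
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Scoring scheme:", nrow(x$substitution_matrix), "x",
      ncol(x$substitution_matrix), "substitution matrix;",
      "gap open", x$gap_open, "/ extend", x$gap_extend, "\n")
  cat("Karlin-Altschul lambda =", x$ka_lambda, ", K =", x$ka_K, "\n")
  invisible(x)
}

# Encode an amino-acid string as 0-based indices into the scheme's matrix.
# Errors name the offending character and its position.
encode_sequence <- function(sequence, scheme, what = "sequence") {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  idx <- match(chars, rownames(scheme$substitution_matrix))
  if (anyNA(idx)) {
    p <- which(is.na(idx))[1L]
    stop("invalid residue '", chars[p], "' at position ", p, " in ", what)
  }
  idx - 1L
}
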