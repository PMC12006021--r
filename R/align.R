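#' Optimal global (Needleman-Wunsch) pairwise alignment
#'
#' Computes the optimal global alignment of two amino-acid sequences under
#' an affine gap model (a gap of length g costs `gap_open +
#' gap_extend * (g - 1)`). Traceback is deterministic with tie order
#' diagonal > up > left. Percent identity is computed over *all* alignment
#' columns, terminal and internal gaps included; X never counts as
#' identical.
#'
#' @param query,subject non-empty amino-acid strings.
#' @param scheme a [scoring_scheme()].
#' @return An object of class `"alignment_result"`: a list with `mode`,
#'   `score`, `aligned_query`, `aligned_subject`, `n_identical`,
#'   `n_columns`, `percent_identity`, `e_value` (`NA` in global mode),
#'   and `query_coverage`.
#' @examples
#' global_align("MKVLI", "MKVLI")$percent_identity
#' @seealso [local_align()], [evalue()]
#' @export
global_align <- function(query, subject, scheme = scoring_scheme()) {
  align_one(query, subject, scheme, local = FALSE)
}

#' Optimal local (Smith-Waterman) pairwise alignment
#'
#' Same machinery as [global_align()] but with the Smith-Waterman zero
#' floor: the reported alignment is the best-scoring segment pair, and a
#' pair with no positive-scoring segment yields score 0 and an empty
#' alignment. Percent identity is computed over the columns of the local
#' alignment (the BLAST `pident` convention). The E-value is
#' `K * m * n * exp(-lambda * score)` with `m`, `n` the full (unaligned)
#' sequence lengths.
#'
#' @inheritParams global_align
#' @return An `"alignment_result"`; see [global_align()].
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  align_one(query, subject, scheme, local = TRUE)
}

align_one <- function(query, subject, scheme, local) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop("query must be a single non-empty sequence")
  if (!is.character(subject) || length(subject) != 1L || !nzchar(subject))
    stop("subject must be a single non-empty sequence")
  q <- encode_sequence(query, scheme, "query")
  s <- encode_sequence(subject, scheme, "subject")
  res <- align_pair_cpp(q, s, scheme$substitution_matrix,
                        scheme$gap_open, scheme$gap_extend, local)
  residues <- rownames(scheme$substitution_matrix)
  dec <- function(v) {
    out <- character(length(v))
    gap <- v < 0L
    out[gap] <- "-"
    out[!gap] <- residues[v[!gap] + 1L]
    paste(out, collapse = "")
  }
  qa <- res$q_aln
  sa <- res$s_aln
  n_col <- length(qa)
  xcode <- match("X", residues) - 1L
  ident <- qa >= 0L & sa >= 0L & qa == sa & qa != xcode
  n_id <- sum(ident)
  m <- length(q); n <- length(s)
  cov <- if (local) {
    if (n_col == 0L) 0 else (res$q_end - res$q_start + 1L) / m
  } else 1
  structure(list(
    mode = if (local) "local" else "global",
    score = res$score,
    aligned_query = dec(qa),
    aligned_subject = dec(sa),
    n_identical = n_id,
    n_columns = n_col,
    percent_identity = if (n_col == 0L) 0 else 100 * n_id / n_col,
    e_value = if (local) evalue(res$score, m, n, scheme) else NA_real_,
    query_coverage = cov),
    class = "alignment_result")
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance alignments scoring at least `score`:
#' `K * m * n * exp(-lambda * score)`. Strictly decreasing in `score`,
#' linear in each sequence length.
#'
#' @param score non-negative alignment score.
#' @param m,n positive lengths of the two (unaligned) sequences.
#' @param scheme a [scoring_scheme()] supplying `ka_lambda` and `ka_K`.
#' @return The E-value, a non-negative number.
#' @examples
#' evalue(0, 100, 100)          # = K * m * n
#' @export
evalue <- function(score, m, n, scheme = scoring_scheme()) {
  if (any(score < 0)) stop("score must be non-negative")
  if (any(m <= 0) || any(n <= 0)) stop("sequence lengths must be positive")
  scheme$ka_K * m * n * exp(-scheme$ka_lambda * score)
}

#' Re-score an aligned sequence pair
#'
#' Sums substitution scores over residue columns and affine penalties over
#' gap runs of a gapped alignment. Used to verify that a reported alignment
#' score is reproduced exactly by its own aligned strings.
#'
#' @param aligned_query,aligned_subject equal-length gapped strings
#'   (`-` = gap).
#' @param scheme a [scoring_scheme()].
#' @return The alignment score.
#' @export
rescore_alignment <- function(aligned_query, aligned_subject,
                              scheme = scoring_scheme()) {
  qa <- strsplit(toupper(aligned_query), "")[[1L]]
  sa <- strsplit(toupper(aligned_subject), "")[[1L]]
  if (length(qa) != length(sa)) stop("aligned strings differ in length")
  m <- scheme$substitution_matrix
  score <- 0
  run <- 0L  # current gap run length (either direction)
  for (k in seq_along(qa)) {
    if (qa[k] == "-" || sa[k] == "-") {
      if (qa[k] == "-" && sa[k] == "-") stop("double gap column")
      run <- run + 1L
      score <- score - if (run == 1L) scheme$gap_open else scheme$gap_extend
    } else {
      run <- 0L
      score <- score + m[qa[k], sa[k]]
    }
  }
  score
}

#' Batch alignment scores
#'
#' Score-only alignment of many query/subject pairs (no traceback); the
#' workhorse behind the screening stage and large property checks.
#'
#' @param queries,subjects character vectors of equal length (or one of
#'   them of length 1, recycled).
#' @param scheme a [scoring_scheme()].
#' @param mode `"global"` or `"local"`.
#' @return Numeric vector of optimal scores.
#' @export
align_scores <- function(queries, subjects, scheme = scoring_scheme(),
                         mode = c("global", "local")) {
  mode <- match.arg(mode)
  n <- max(length(queries), length(subjects))
  queries <- rep_len(queries, n)
  subjects <- rep_len(subjects, n)
  qs <- lapply(queries, encode_sequence, scheme = scheme)
  ss <- lapply(subjects, encode_sequence, scheme = scheme)
  score_pairs_cpp(qs, ss, scheme$substitution_matrix,
                  scheme$gap_open, scheme$gap_extend, mode == "local")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment: score %g, %d/%d identical (%.1f%%)\n",
              x$mode, x$score, x$n_identical, x$n_columns,
              x$percent_identity))
  if (!is.na(x$e_value)) cat(sprintf("E-value: %.3g\n", x$e_value))
  w <- 60L
  nc <- nchar(x$aligned_query)
  for (i in seq(1L, max(nc, 1L), by = w)) {
    cat(substr(x$aligned_query, i, min(i + w - 1L, nc)), "\n")
    cat(substr(x$aligned_subject, i, min(i + w - 1L, nc)), "\n\n")
  }
  invisible(x)
}
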