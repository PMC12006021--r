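# The 10 unordered element-pair contact classes over {C, N, O, X}
CONTACT_CLASSES <- c("CC", "CN", "CO", "CX", "NN", "NO", "NX", "OO", "OX",
                     "XX")

# Collapse an element symbol to its contact class letter
element_class <- function(element) {
  e <- toupper(element)
  ifelse(e %in% c("C", "N", "O"), e, "X")
}

#' Protein-ligand atomic contact profile
#'
#' Counts every (protein heavy atom, ligand heavy atom) pair within a
#' Euclidean distance cutoff and classifies each pair into one of the 10
#' unordered element-pair classes over \{C, N, O, X\} (X = any other
#' element). Hydrogens are excluded. This is the contact census behind the
#' linear affinity predictor of [predict_affinity()].
#'
#' @param complex a [complex_structure()].
#' @param cutoff contact distance cutoff in Angstrom (default 10.5, the
#'   conventional small-molecule contact radius for this class of model).
#' @return An object of class `"contact_profile"`: a list with `counts`
#'   (named integer vector over the 10 classes), `total` and
#'   `cutoff_used`.
#' @export
contact_profile <- function(complex, cutoff = 10.5) {
  stopifnot(inherits(complex, "complex_structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- complex$atoms[toupper(complex$atoms$element) != "H", , drop = FALSE]
  prot <- at[at$entity == "protein", , drop = FALSE]
  lig <- at[at$entity == "ligand", , drop = FALSE]
  if (!nrow(lig)) stop("complex has no ligand heavy atoms")
  counts <- setNames(integer(length(CONTACT_CLASSES)), CONTACT_CLASSES)
  if (nrow(prot)) {
    pm <- as.matrix(prot[, c("x", "y", "z")])
    lm <- as.matrix(lig[, c("x", "y", "z")])
    d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * pm %*% t(lm)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      pc <- element_class(prot$element)[hit[, 1L]]
      lc <- element_class(lig$element)[hit[, 2L]]
      cls <- ifelse(pc <= lc, paste0(pc, lc), paste0(lc, pc))
      tab <- table(cls)
      counts[names(tab)] <- as.integer(tab)
    }
  }
  structure(list(counts = counts, total = sum(counts),
                 cutoff_used = cutoff),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat("Contact profile (cutoff", x$cutoff_used, "A):",
      x$total, "contacts\n")
  print(x$counts)
  invisible(x)
}

#' Linear contact-based affinity model
#'
#' A predicted binding free energy that is linear in the 10 contact-class
#' counts: \eqn{\Delta G = b_0 + \sum_c b_c n_c} (kcal/mol; more negative =
#' stronger predicted binding).
#'
#' @param intercept intercept in kcal/mol.
#' @param coefficients named numeric vector with one coefficient per
#'   contact class (`CC`, `CN`, ..., `XX`), kcal/mol per contact.
#' @return An object of class `"affinity_model"`.
#' @seealso [default_affinity_model()], [read_affinity_model()]
#' @export
affinity_model <- function(intercept, coefficients) {
  miss <- setdiff(CONTACT_CLASSES, names(coefficients))
  if (length(miss))
    stop("missing coefficient(s): ", paste(miss, collapse = ", "))
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients[CONTACT_CLASSES]),
            class = "affinity_model")
}

#' Read an affinity model from a key-value text file
#'
#' The format is one `key = value` pair per line (`#` comments allowed);
#' keys are `intercept` plus the 10 contact classes.
#'
#' @param path path to the model file.
#' @return An [affinity_model()].
#' @export
read_affinity_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  names(vals) <- keys
  if (!"intercept" %in% keys) stop("model file lacks 'intercept'")
  affinity_model(vals[["intercept"]], vals[setdiff(keys, "intercept")])
}

#' Package default affinity model
#'
#' Loads the synthetic default coefficient set shipped with the package
#' (`extdata/affinity_model_synthetic_default.txt`). These defaults are
#' illustrative calibration values chosen by the package authors, not a
#' published parameterisation; replace them with your own model file via
#' [read_affinity_model()] for quantitative work.
#'
#' @return An [affinity_model()].
#' @export
default_affinity_model <- function() {
  read_affinity_model(system.file("extdata",
                                  "affinity_model_synthetic_default.txt",
                                  package = "metaprom", mustWork = TRUE))
}

#' Predict binding affinity from a contact profile
#'
#' @param profile a [contact_profile()].
#' @param model an [affinity_model()]; default [default_affinity_model()].
#' @return Predicted \eqn{\Delta G} in kcal/mol.
#' @export
predict_affinity <- function(profile, model = default_affinity_model()) {
  stopifnot(inherits(profile, "contact_profile"),
            inherits(model, "affinity_model"))
  model$intercept +
    sum(model$coefficients * as.numeric(profile$counts[CONTACT_CLASSES]))
}

#' Binding pocket residues of a posed complex
#'
#' Protein residues with at least one heavy atom within `pocket_cutoff` of
#' any ligand heavy atom, in sequence order.
#'
#' @param complex a [complex_structure()].
#' @param pocket_cutoff distance cutoff in Angstrom (default 5.0, a
#'   conventional interacting-residue threshold).
#' @return A data.frame with columns `chain`, `resno`, `resname`.
#' @export
pocket_residues <- function(complex, pocket_cutoff = 5.0) {
  stopifnot(inherits(complex, "complex_structure"))
  at <- complex$atoms[toupper(complex$atoms$element) != "H", , drop = FALSE]
  prot <- at[at$entity == "protein", , drop = FALSE]
  lig <- at[at$entity == "ligand", , drop = FALSE]
  if (!nrow(lig)) stop("complex has no ligand heavy atoms")
  empty <- data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), stringsAsFactors = FALSE)
  if (!nrow(prot)) return(empty)
  pm <- as.matrix(prot[, c("x", "y", "z")])
  lm <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * pm %*% t(lm)
  near <- apply(d2 <= pocket_cutoff^2, 1L, any)
  if (!any(near)) return(empty)
  res <- unique(prot[near, c("chain", "resno", "resname"), drop = FALSE])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare the binding pocket of a reference complex with another sequence
#'
#' Globally aligns the reference chain sequence to `comparison_sequence`
#' and projects each pocket residue through the alignment, classifying it
#' as `identical`, `substituted`, or `deleted` (pocket residue aligned to a
#' gap). Insertions in the comparison sequence falling between two pocket
#' residues that are consecutive in the reference chain are counted in
#' `n_insertions`. An alignment identity below 15% aborts: the projection
#' would be unreliable.
#'
#' @param reference a [complex_structure()] with a bound ligand.
#' @param comparison_sequence amino-acid string to project the pocket onto.
#' @param scheme a [scoring_scheme()].
#' @param pocket_cutoff pocket definition cutoff in Angstrom.
#' @param chain reference chain; default is the chain carrying the most
#'   pocket residues.
#' @return An object of class `"pocket_comparison"`: list with `residues`
#'   (per-pocket-residue data.frame: `chain`, `resno`, `resname`,
#'   `ref_aa`, `cmp_aa`, `status`), `n_identical`, `n_substituted`,
#'   `n_deleted`, `n_insertions`, `alignment`.
#' @export
compare_pockets <- function(reference, comparison_sequence,
                            scheme = scoring_scheme(), pocket_cutoff = 5.0,
                            chain = NULL) {
  stopifnot(inherits(reference, "complex_structure"))
  pocket <- pocket_residues(reference, pocket_cutoff)
  if (!nrow(pocket)) stop("reference complex has an empty binding pocket")
  if (is.null(chain)) chain <- names(which.max(table(pocket$chain)))
  pocket <- pocket[pocket$chain == chain, , drop = FALSE]
  ref_seq <- complex_sequence(reference, chain)
  aln <- global_align(ref_seq, comparison_sequence, scheme)
  if (aln$percent_identity < 15)
    stop("pocket projection unreliable: alignment identity ",
         round(aln$percent_identity, 1), "% < 15%")
  qa <- strsplit(aln$aligned_query, "")[[1L]]
  sa <- strsplit(aln$aligned_subject, "")[[1L]]
  # reference residue index (1..n) per alignment column; NA at ref gaps
  ref_idx <- ifelse(qa == "-", NA_integer_, cumsum(qa != "-"))
  # pocket residues in chain order; residue k of the chain sequence
  at <- reference$atoms[reference$atoms$entity == "protein" &
                          reference$atoms$chain == chain, , drop = FALSE]
  resnos <- sort(unique(at$resno))
  pocket_k <- match(pocket$resno, resnos)
  col_of <- match(pocket_k, ref_idx)
  status <- character(nrow(pocket))
  cmp_aa <- character(nrow(pocket))
  for (i in seq_len(nrow(pocket))) {
    cc <- col_of[i]
    cmp_aa[i] <- sa[cc]
    status[i] <- if (sa[cc] == "-") "deleted"
      else if (sa[cc] == qa[cc]) "identical" else "substituted"
  }
  # insertion columns flanked by consecutive-in-reference pocket residues
  n_ins <- 0L
  gap_cols <- which(qa == "-")
  pocket_set <- pocket_k
  for (g in gap_cols) {
    if (g == 1L || g == length(ref_idx)) next
    before <- ref_idx[seq_len(g - 1L)]
    before <- before[!is.na(before)]
    after <- ref_idx[seq(g + 1L, length(ref_idx))]
    after <- after[!is.na(after)]
    if (!length(before) || !length(after)) next
    b <- before[length(before)]; a <- after[1L]
    if (a == b + 1L && b %in% pocket_set && a %in% pocket_set)
      n_ins <- n_ins + 1L
  }
  residues <- data.frame(chain = pocket$chain, resno = pocket$resno,
                         resname = pocket$resname,
                         ref_aa = qa[col_of], cmp_aa = cmp_aa,
                         status = status, stringsAsFactors = FALSE)
  structure(list(residues = residues,
                 n_identical = sum(status == "identical"),
                 n_substituted = sum(status == "substituted"),
                 n_deleted = sum(status == "deleted"),
                 n_insertions = n_ins,
                 alignment = aln),
            class = "pocket_comparison")
}

#' @export
print.pocket_comparison <- function(x, ...) {
  cat("Pocket comparison:", nrow(x$residues), "pocket residues;",
      x$n_identical, "identical,", x$n_substituted, "substituted,",
      x$n_deleted, "deleted;", x$n_insertions, "insertion(s)\n")
  print(x$residues)
  invisible(x)
}
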