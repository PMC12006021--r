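#' Construct a protein-ligand complex structure
#'
#' Container for a posed complex: an atom table plus the ligand residue
#' name. Atom entities are `"protein"` or `"ligand"`; coordinates are in
#' Angstrom.
#'
#' @param atoms data.frame with columns `entity`, `element`, `atom_name`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z`.
#' @param ligand_name the ligand residue name (e.g. `"LIG"`).
#' @return An object of class `"complex_structure"`.
#' @export
complex_structure <- function(atoms, ligand_name) {
  need <- c("entity", "element", "atom_name", "resname", "resno", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!any(atoms$entity == "protein")) stop("complex has no protein atoms")
  if (!any(atoms$entity == "ligand")) stop("complex has no ligand atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(is.na(atoms$element) | !nzchar(atoms$element)))
    stop("empty element symbol(s) in atom table")
  structure(list(atoms = as.data.frame(atoms)[need],
                 ligand_name = ligand_name),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  np <- sum(x$atoms$entity == "protein")
  nl <- sum(x$atoms$entity == "ligand")
  cat("Protein-ligand complex:", np, "protein atoms,", nl,
      "ligand atoms (", x$ligand_name, ")\n")
  invisible(x)
}

# Element from a PDB atom name when the element column is blank.
# Protein atom names follow the remoteness convention (CA, CB, OG1, NZ,
# ...): the element is the first alphabetic character once digits are
# stripped. For hetero atoms, recognised two-letter halogens/metals are
# honoured first.
infer_element <- function(atom_name, hetero = FALSE) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "CU", "NI")
  out <- character(length(nm))
  for (k in seq_along(nm)) {
    if (!nzchar(nm[k])) stop("cannot infer element from atom name '",
                             atom_name[k], "'")
    if (hetero && substr(nm[k], 1L, 2L) %in% two)
      out[k] <- substr(nm[k], 1L, 2L)
    else out[k] <- substr(nm[k], 1L, 1L)
  }
  out
}

#' Read a posed protein-ligand complex from a PDB file
#'
#' PDB parsing is delegated to \pkg{bio3d}. Protein atoms are the `ATOM`
#' records; ligand atoms are the `HETATM` records whose residue name
#' matches `ligand_name`. Waters are excluded. The element symbol is taken
#' from the PDB element column when present, otherwise inferred from the
#' atom name. Hydrogens are retained in the atom table (downstream contact
#' analysis excludes them).
#'
#' @param path path to a PDB file.
#' @param ligand_name residue name identifying the ligand.
#' @return A [complex_structure()].
#' @export
read_complex <- function(path, ligand_name) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  is_prot <- at$type == "ATOM"
  is_lig <- at$type == "HETATM" & at$resid == ligand_name
  if (!any(is_lig))
    stop("ligand '", ligand_name, "' not found in ", path)
  if (!any(is_prot))
    stop("no protein (ATOM) records in ", path)
  at <- at[is_prot | is_lig, , drop = FALSE]
  entity <- ifelse(at$type == "ATOM", "protein", "ligand")
  ele <- at$elesy
  blank <- is.na(ele) | !nzchar(trimws(ele))
  ele[!blank] <- toupper(trimws(ele[!blank]))
  if (any(blank))
    ele[blank] <- infer_element(at$elety[blank],
                                hetero = entity[blank] == "ligand")
  chain <- ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain)
  complex_structure(
    data.frame(entity = entity, element = ele,
               atom_name = trimws(at$elety), resname = at$resid,
               resno = at$resno, chain = chain,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    ligand_name = ligand_name)
}

#' Write a complex structure to a PDB file
#'
#' @param complex a [complex_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(complex, path) {
  at <- complex$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$entity == "protein", "ATOM", "HETATM"),
                   resno = at$resno, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$atom_name,
                   chain = at$chain, elesy = at$element)
  invisible(path)
}

#' Extract the one-letter protein sequence of a complex chain
#'
#' @param complex a [complex_structure()].
#' @param chain chain id; default is the first protein chain.
#' @return A one-letter amino-acid string (unknown residues become X).
#' @export
complex_sequence <- function(complex, chain = NULL) {
  at <- complex$atoms[complex$atoms$entity == "protein", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop("no protein atoms in chain ", chain)
  res <- at[!duplicated(at$resno), , drop = FALSE]
  res <- res[order(res$resno), , drop = FALSE]
  one <- suppressWarnings(bio3d::aa321(res$resname))
  one[is.na(one) | !one %in% AA21] <- "X"
  paste(one, collapse = "")
}
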