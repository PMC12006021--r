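#' Read a protein FASTA file
#'
#' FASTA parsing is delegated to \pkg{Biostrings}; this wrapper enforces the
#' conventions the pipeline relies on: record ids are the first
#' whitespace-delimited header token, sequences are upper-cased, record
#' order is preserved, duplicate ids are an error, selenocysteine (U) and
#' pyrrolysine (O) are mapped to X with a warning, and any character outside
#' the 20 standard residues plus X is an error that names the position.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  mapped <- grepl("[UO]", seqs)
  if (any(mapped)) {
    warning("mapping selenocysteine/pyrrolysine (U/O) to X in ",
            sum(mapped), " record(s)")
    seqs <- gsub("[UO]", "X", seqs)
  }
  ok <- paste(AA21, collapse = "")
  for (k in seq_along(seqs)) {
    bad <- regexpr(paste0("[^", ok, "]"), seqs[k])
    if (bad > 0L)
      stop("invalid character '", substr(seqs[k], bad, bad),
           "' at position ", bad, " in record '", ids[k], "'")
    if (!nzchar(seqs[k])) stop("empty sequence in record '", ids[k], "'")
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#'
#' @param records a data.frame with `id` and `sequence` columns (as returned
#'   by [read_fasta()]) or a named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse GTDB-style lineage strings
#'
#' Lineages use rank prefixes `d__,p__,c__,o__,f__,g__,s__` separated by
#' `;`. Absent trailing ranks are tolerated (permissive mode); the species
#' field keeps the full binomial (genus included). A malformed lineage
#' yields `NA` in the `ok` column rather than an error so that callers can
#' report rejected entries.
#'
#' @param lineage character vector of lineage strings.
#' @return A data.frame with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species` (all `NA` when the rank is absent) and a
#'   logical `ok` flag.
#' @export
parse_lineage <- function(lineage) {
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  out <- as.data.frame(matrix(NA_character_, length(lineage), 7L,
                              dimnames = list(NULL, ranks)),
                       stringsAsFactors = FALSE)
  out$ok <- FALSE
  for (k in seq_along(lineage)) {
    if (is.na(lineage[k]) || !nzchar(trimws(lineage[k]))) next
    parts <- trimws(strsplit(lineage[k], ";", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    if (length(parts) > 7L) next
    pref <- substr(parts, 1L, 3L)
    pos <- match(pref, prefixes)
    # ranks must be recognised and appear in canonical order
    if (anyNA(pos) || is.unsorted(pos, strictly = TRUE)) next
    vals <- substring(parts, 4L)
    vals[!nzchar(vals)] <- NA_character_
    out[k, pos] <- vals
    out$ok[k] <- TRUE
  }
  out
}

#' Read a metaproteome annotation table and join sequences
#'
#' The table is a TSV with header columns `protein_id`, `mag_id`, `biome`,
#' `lineage` and `function`, describing the proteins of one or more
#' body-site catalogues. Every protein must have a sequence in the
#' companion FASTA; unknown biome values and missing sequences are errors.
#' Rows whose lineage fails to parse are dropped with a warning and
#' attached to the result as attribute `"rejected"` (never silently).
#'
#' @param path path to the annotation TSV.
#' @param fasta a FASTA path or a data.frame from [read_fasta()].
#' @return A data.frame with columns `protein_id`, `sequence`, `mag_id`,
#'   `biome`, `lineage`, `species`, `phylum`, `function_annotation`.
#' @export
read_annotation_table <- function(path, fasta) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "mag_id", "biome", "lineage", "function")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  bad_biome <- setdiff(unique(tab$biome), BIOMES)
  if (length(bad_biome))
    stop("unknown biome value(s): ", paste(bad_biome, collapse = ", "),
         " (expected ", paste(BIOMES, collapse = "/"), ")")
  dup <- tab$protein_id[duplicated(paste(tab$biome, tab$protein_id))]
  if (length(dup))
    stop("protein_id not unique within biome: ",
         paste(unique(dup), collapse = ", "))
  if (is.character(fasta)) fasta <- read_fasta(fasta)
  seq <- fasta$sequence[match(tab$protein_id, fasta$id)]
  if (anyNA(seq))
    stop("protein(s) in annotation table absent from FASTA: ",
         paste(tab$protein_id[is.na(seq)], collapse = ", "))
  lin <- parse_lineage(tab$lineage)
  out <- data.frame(protein_id = tab$protein_id, sequence = seq,
                    mag_id = tab$mag_id, biome = tab$biome,
                    lineage = tab$lineage, species = lin$species,
                    phylum = lin$phylum,
                    function_annotation = tab[["function"]],
                    stringsAsFactors = FALSE)
  if (any(!lin$ok)) {
    rejected <- out[!lin$ok, , drop = FALSE]
    warning(nrow(rejected), " entr(ies) rejected: unparseable lineage (",
            paste(head(rejected$protein_id, 5L), collapse = ", "), ")")
    out <- out[lin$ok, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "rejected") <- rejected
  }
  out
}

#' Read drug-target protein records
#'
#' Joins a target FASTA with its metadata sidecar TSV (columns `target_id`,
#' `target_organism`, `target_class`, `function_label`, `drug_ids`;
#' `drug_ids` is a comma-separated list, possibly empty).
#'
#' @param fasta_path FASTA of target sequences.
#' @param meta_path metadata TSV.
#' @return A data.frame, one row per target, `drug_ids` kept as a
#'   comma-separated string.
#' @export
read_targets <- function(fasta_path, meta_path) {
  fa <- read_fasta(fasta_path)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("target_id", "target_organism", "target_class", "function_label",
            "drug_ids")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("target table lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(meta$target_class), c("human", "pathogen"))
  if (length(bad))
    stop("target_class must be 'human' or 'pathogen', got: ",
         paste(bad, collapse = ", "))
  seq <- fa$sequence[match(meta$target_id, fa$id)]
  if (anyNA(seq))
    stop("target(s) absent from FASTA: ",
         paste(meta$target_id[is.na(seq)], collapse = ", "))
  data.frame(target_id = meta$target_id, sequence = seq,
             target_organism = meta$target_organism,
             target_class = meta$target_class,
             function_label = meta$function_label,
             drug_ids = meta$drug_ids, stringsAsFactors = FALSE)
}

#' Read a pathogen species catalog
#'
#' A CSV listing bacterial species recorded as capable of causing human
#' infection (one binomial per row; a `species` header is optional). Names
#' are normalised with [normalize_species()].
#'
#' @param path path to the CSV.
#' @return Character vector of normalised species names, class
#'   `"pathogen_catalog"`.
#' @export
read_pathogen_catalog <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  col <- if ("species" %in% names(tab)) tab$species else tab[[1L]]
  # a headerless single-column file loses its first entry to the header
  if (!"species" %in% names(tab) && !identical(names(tab), "V1"))
    col <- c(gsub("\\.", " ", names(tab)[1L]), col)
  species <- unique(normalize_species(col))
  species <- species[!is.na(species)]
  if (!length(species)) stop("empty pathogen catalog: ", path)
  structure(species, class = "pathogen_catalog")
}

#' Read a drug side-effect table
#'
#' TSV with columns `drug_id`, `symptom` (MedDRA preferred term) and `soc`
#' (system organ class). `(drug_id, symptom)` pairs must be unique and
#' every row must carry a non-empty `soc`.
#'
#' @param path path to the TSV.
#' @return A data.frame with the three columns.
#' @export
read_side_effect_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "symptom", "soc")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("side-effect table lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(tab$drug_id, tab$symptom, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (drug_id, symptom) pair(s) in side-effect table")
  if (any(is.na(tab$soc) | !nzchar(trimws(tab$soc))))
    stop("side-effect rows with empty system organ class")
  tab[need]
}

#' Read drug-to-target links
#' @param path TSV with columns `drug_id`, `target_id`.
#' @return A data.frame with the two columns, duplicates removed.
#' @export
read_drug_target_links <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "target_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("link table lacks column(s): ", paste(miss, collapse = ", "))
  unique(tab[need])
}
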