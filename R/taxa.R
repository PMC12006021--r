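#' Normalise bacterial species names
#'
#' Lowercases, collapses internal whitespace and truncates to the binomial
#' (first two tokens), so that GTDB lineage species and catalog names
#' written with different conventions compare equal.
#'
#' @param x character vector of species names.
#' @return Normalised names (`NA` stays `NA`; empty strings become `NA`).
#' @export
normalize_species <- function(x) {
  out <- tolower(trimws(gsub("\\s+", " ", x)))
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  toks <- strsplit(out, " ", fixed = TRUE)
  vapply(toks, function(t) {
    if (length(t) == 0L || all(is.na(t))) NA_character_
    else paste(t[seq_len(min(2L, length(t)))], collapse = " ")
  }, "")
}

#' Three-biome species overlap
#'
#' Deduplicates the species hit in each biome and computes the seven
#' exclusive regions of the three-set Venn diagram. Hits without a species
#' rank (`NA`) are excluded from the overlap but tallied separately.
#'
#' @param hits an `"offtarget_hits"` data.frame (needs `biome` and
#'   `species` columns), or any data.frame with those columns.
#' @return An object of class `"species_overlap"`: list with `sets` (per
#'   biome species vectors), `regions` (7 named counts), `set_sizes`,
#'   `union_size`, `n_na` (per-biome count of species-less hits).
#' @export
species_overlap <- function(hits) {
  sets <- lapply(setNames(BIOMES, BIOMES), function(b) {
    sp <- hits$species[hits$biome == b]
    sort(unique(sp[!is.na(sp)]))
  })
  regions <- venn_regions(sets$gut, sets$oral, sets$vaginal)
  n_na <- vapply(BIOMES, function(b)
    sum(hits$biome == b & is.na(hits$species)), 0L)
  out <- structure(list(sets = sets, regions = regions,
                        set_sizes = lengths(sets),
                        union_size = length(unique(unlist(sets))),
                        n_na = n_na),
                   class = "species_overlap")
  stopifnot(sum(out$regions) == out$union_size)  # Venn conservation
  out
}

#' Exclusive regions of a three-set Venn diagram
#'
#' @param a,b,c character vectors (duplicates ignored).
#' @return Named integer vector of the 7 exclusive region counts:
#'   `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`.
#' @export
venn_regions <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  in_ab <- intersect(a, b); in_ac <- intersect(a, c); in_bc <- intersect(b, c)
  abc <- intersect(in_ab, c)
  c(a_only = length(setdiff(a, union(b, c))),
    b_only = length(setdiff(b, union(a, c))),
    c_only = length(setdiff(c, union(a, b))),
    ab = length(setdiff(in_ab, abc)),
    ac = length(setdiff(in_ac, abc)),
    bc = length(setdiff(in_bc, abc)),
    abc = length(abc))
}

#' @export
print.species_overlap <- function(x, ...) {
  cat("Species overlap across biomes (gut/oral/vaginal):",
      paste(x$set_sizes, collapse = "/"), "species;",
      "union", x$union_size, "\n")
  print(x$regions)
  invisible(x)
}

#' Per-target phylum composition of hits
#'
#' Counts hit proteins per target per phylum (per-protein counting, the
#' stacked-bar view). Hits whose lineage lacks a phylum land in the `"NA"`
#' bucket; a `"Total"` row per target is appended. GTDB and NCBI phylum
#' synonyms (e.g. Firmicutes / Bacillota) are *not* merged unless a
#' synonym map is supplied.
#'
#' @param hits an `"offtarget_hits"` data.frame.
#' @param synonyms optional named character vector mapping phylum names to
#'   a canonical spelling (e.g. `c(Bacillota = "Firmicutes")`); off by
#'   default.
#' @return A data.frame `target_id`, `phylum`, `n`, with a `"Total"` row
#'   per target.
#' @export
phylum_composition <- function(hits, synonyms = NULL) {
  if (!nrow(hits))
    return(data.frame(target_id = character(0), phylum = character(0),
                      n = integer(0), stringsAsFactors = FALSE))
  ph <- hits$phylum
  if (!is.null(synonyms)) {
    m <- match(ph, names(synonyms))
    ph[!is.na(m)] <- synonyms[m[!is.na(m)]]
  }
  ph[is.na(ph)] <- "NA"
  tab <- aggregate(list(n = ph), list(target_id = hits$target_id,
                                      phylum = ph), length)
  tot <- aggregate(list(n = tab$n), list(target_id = tab$target_id), sum)
  tot$phylum <- "Total"
  out <- rbind(tab[c("target_id", "phylum", "n")],
               tot[c("target_id", "phylum", "n")])
  out <- out[order(out$target_id, out$phylum == "Total", out$phylum), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify hit species as pathogenic / non-pathogenic / NA
#'
#' Unique-species counting: each species observed for a (target class,
#' biome) cell is classified once. Species present in the catalog are
#' pathogenic, species absent are non-pathogenic, and hits without a
#' species rank form the `NA` class (reported, not dropped). Matching is
#' case- and whitespace-insensitive via [normalize_species()].
#'
#' @param hits an `"offtarget_hits"` data.frame.
#' @param catalog a [read_pathogen_catalog()] object (or character vector
#'   of species names).
#' @return An object of class `"pathogenicity_table"`: list with `counts`
#'   (per target_class x biome: `n_pathogenic`, `n_non_pathogenic`,
#'   `n_na`) and `species` (per-species classification).
#' @export
classify_pathogenicity <- function(hits, catalog) {
  if (!length(catalog)) stop("empty pathogen catalog")
  cat_norm <- unique(normalize_species(unclass(catalog)))
  key <- unique(hits[c("target_class", "biome", "species")])
  key$species_norm <- normalize_species(key$species)
  key <- key[!duplicated(key[c("target_class", "biome", "species_norm")]), ,
             drop = FALSE]
  key$class <- ifelse(is.na(key$species_norm), "NA",
                      ifelse(key$species_norm %in% cat_norm, "pathogenic",
                             "non_pathogenic"))
  grid <- expand.grid(target_class = c("human", "pathogen"), biome = BIOMES,
                      stringsAsFactors = FALSE)
  cnt <- function(cl) vapply(seq_len(nrow(grid)), function(i)
    sum(key$target_class == grid$target_class[i] &
          key$biome == grid$biome[i] & key$class == cl), 0L)
  grid$n_pathogenic <- cnt("pathogenic")
  grid$n_non_pathogenic <- cnt("non_pathogenic")
  # species-less hits form the NA class: distinct unnamed organisms (MAGs)
  grid$n_na <- vapply(seq_len(nrow(grid)), function(i) {
    sub <- hits[hits$target_class == grid$target_class[i] &
                  hits$biome == grid$biome[i] & is.na(hits$species), ,
                drop = FALSE]
    if (!nrow(sub)) 0L else length(unique(sub$mag_id))
  }, 0L)
  structure(list(counts = grid,
                 species = key[order(key$target_class, key$biome,
                                     key$species), , drop = FALSE]),
            class = "pathogenicity_table")
}

#' @export
print.pathogenicity_table <- function(x, ...) {
  cat("Pathogenicity classification of hit species:\n")
  print(x$counts)
  invisible(x)
}
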