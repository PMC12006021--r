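#' Pipeline run configuration
#'
#' Collects input paths and every threshold of the analysis: the strict
#' 30% identity call threshold, the strict 50% function-concordance
#' cutoff, the E-value cutoff for candidate discovery, the 10.5 A contact
#' and 5.0 A pocket cutoffs, and the strict 10% prevalence-change filter.
#' Configurations round-trip through YAML unchanged
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param targets_fasta,targets_meta drug-target inputs ([read_targets()]).
#' @param meta_fasta,meta_annot named character vectors (by biome) of
#'   metaproteome FASTA / annotation TSV paths.
#' @param output_dir directory for stage outputs and the run manifest.
#' @param pathogen_catalog optional catalog CSV; `NULL` skips the
#'   pathogenicity stage.
#' @param side_effects,links optional side-effect TSV and drug-target-link
#'   TSV; both required for the clinical stage.
#' @param complexes optional data.frame with columns `path`, `ligand` and
#'   optionally `comparison_protein_id` (a metaproteome protein to project
#'   the pocket onto); `NULL` skips the structure stage.
#' @param affinity_model optional model file path
#'   ([read_affinity_model()]); default model used when `NULL`.
#' @param similarity_threshold,function_threshold,evalue_cutoff,identity_mode
#'   screening thresholds; see [screen_targets()].
#' @param contact_cutoff,pocket_cutoff structural cutoffs in Angstrom.
#' @param min_change strict percent-change filter for
#'   [prevalence_change()].
#' @param seed seed for any seeded sub-analysis (permutation null).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(targets_fasta, targets_meta, meta_fasta, meta_annot,
                       output_dir, pathogen_catalog = NULL,
                       side_effects = NULL, links = NULL, complexes = NULL,
                       affinity_model = NULL, similarity_threshold = 30,
                       function_threshold = 50, evalue_cutoff = 1e-6,
                       identity_mode = "global", contact_cutoff = 10.5,
                       pocket_cutoff = 5.0, min_change = 10, seed = 1) {
  if (!(similarity_threshold > 0 && similarity_threshold <= 100))
    stop("similarity_threshold must be in (0, 100]")
  if (!(function_threshold > 0 && function_threshold <= 100))
    stop("function_threshold must be in (0, 100]")
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive")
  if (!identity_mode %in% c("global", "local"))
    stop("identity_mode must be 'global' or 'local'")
  if (contact_cutoff <= 0 || pocket_cutoff <= 0)
    stop("structural cutoffs must be positive")
  if (min_change < 0) stop("min_change must be non-negative")
  if (is.null(names(meta_fasta)) || is.null(names(meta_annot)) ||
      !setequal(names(meta_fasta), names(meta_annot)))
    stop("meta_fasta and meta_annot must be named by the same biomes")
  if (!is.null(complexes)) {
    complexes <- as.data.frame(complexes, stringsAsFactors = FALSE)
    if (!all(c("path", "ligand") %in% names(complexes)))
      stop("complexes needs 'path' and 'ligand' columns")
    if (is.null(complexes$comparison_protein_id))
      complexes$comparison_protein_id <- NA_character_
  }
  structure(list(targets_fasta = targets_fasta, targets_meta = targets_meta,
                 meta_fasta = meta_fasta, meta_annot = meta_annot,
                 output_dir = output_dir,
                 pathogen_catalog = pathogen_catalog,
                 side_effects = side_effects, links = links,
                 complexes = complexes, affinity_model = affinity_model,
                 similarity_threshold = similarity_threshold,
                 function_threshold = function_threshold,
                 evalue_cutoff = evalue_cutoff,
                 identity_mode = identity_mode,
                 contact_cutoff = contact_cutoff,
                 pocket_cutoff = pocket_cutoff, min_change = min_change,
                 seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$meta_fasta <- as.list(x$meta_fasta)
  x$meta_annot <- as.list(x$meta_annot)
  if (!is.null(x$complexes)) x$complexes <- as.list(x$complexes)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$meta_fasta <- unlist(x$meta_fasta)
  x$meta_annot <- unlist(x$meta_annot)
  if (!is.null(x$complexes))
    x$complexes <- as.data.frame(x$complexes, stringsAsFactors = FALSE)
  do.call(run_config, x)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  x <- unclass(config)
  x$output_dir <- NULL  # where outputs go does not change what they are
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

write_stage_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full promiscuity analysis pipeline
#'
#' Executes screen -> taxa -> clinical (and structure when complexes are
#' configured) in order, writing one TSV per stage output plus a JSON run
#' manifest (config hash, input checksums, per-stage row counts) into
#' `config$output_dir`. Reruns on identical inputs and configuration
#' produce byte-identical outputs. A stage failure aborts with the stage
#' name; a missing pathogen catalog or missing clinical inputs skip their
#' stages with a warning.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- list()
  out <- function(df, file) write_stage_tsv(df, file.path(config$output_dir,
                                                          file), hash)

  message("[io] reading inputs")
  targets <- stage("io", read_targets(config$targets_fasta,
                                      config$targets_meta))
  meta <- stage("io", do.call(rbind, lapply(names(config$meta_fasta),
    function(b) read_annotation_table(config$meta_annot[[b]],
                                      config$meta_fasta[[b]]))))

  message("[screen] aligning ", nrow(targets), " targets x ", nrow(meta),
          " metaproteome proteins")
  hits <- stage("screen",
                screen_targets(targets, meta,
                               similarity_threshold =
                                 config$similarity_threshold,
                               evalue_cutoff = config$evalue_cutoff,
                               identity_mode = config$identity_mode))
  counts$hits <- nrow(hits)
  out(as.data.frame(hits), "hits.tsv")
  summ <- screen_summary(hits)
  out(summ$by_group, "screen_summary.tsv")
  out(identical_matches(hits), "identical_matches.tsv")
  fc <- stage("screen", function_concordance(hits,
                                             config$function_threshold))
  counts$function_concordance <- nrow(fc)
  out(fc, "function_concordance.tsv")

  message("[taxa] aggregating lineages")
  ov <- stage("taxa", species_overlap(hits))
  venn_df <- data.frame(region = names(ov$regions),
                        n_species = as.integer(ov$regions))
  venn_df <- rbind(venn_df,
                   data.frame(region = paste0("size_", BIOMES),
                              n_species = as.integer(ov$set_sizes)))
  out(venn_df, "venn.tsv")
  pc_tab <- stage("taxa", phylum_composition(hits))
  counts$phylum_rows <- nrow(pc_tab)
  out(pc_tab, "phylum_composition.tsv")
  patho <- NULL
  if (!is.null(config$pathogen_catalog)) {
    catalog <- stage("taxa", read_pathogen_catalog(config$pathogen_catalog))
    patho <- stage("taxa", classify_pathogenicity(hits, catalog))
    out(patho$counts, "pathogenicity.tsv")
  } else warning("no pathogen catalog configured: pathogenicity stage ",
                 "skipped")

  clinical <- NULL
  if (!is.null(config$side_effects) && !is.null(config$links)) {
    message("[clinical] side-effect prevalence analysis")
    se <- stage("clinical", read_side_effect_table(config$side_effects))
    links <- stage("clinical", read_drug_target_links(config$links))
    assignment <- stage("clinical", assign_groups(targets, hits, links))
    part <- stage("clinical", symptom_partition(assignment, se))
    out(part$table, "symptom_partition.tsv")
    counts$symptoms <- nrow(part$table)
    prev <- stage("clinical",
                  prevalence_change(assignment, se,
                                    min_change = config$min_change))
    out(as.data.frame(prev), "prevalence_change.tsv")
    counts$enriched_symptoms <- nrow(prev)
    out(soc_rollup(prev), "soc_rollup.tsv")
    clinical <- list(assignment = assignment, partition = part,
                     prevalence = prev)
  } else warning("side-effect table or links not configured: clinical ",
                 "stage skipped")

  structure_res <- NULL
  if (!is.null(config$complexes) && nrow(config$complexes)) {
    message("[structure] contact and pocket analysis")
    model <- if (is.null(config$affinity_model)) default_affinity_model()
      else read_affinity_model(config$affinity_model)
    crows <- list(); prows <- list(); pkrows <- list()
    for (k in seq_len(nrow(config$complexes))) {
      cx <- stage("structure", read_complex(config$complexes$path[k],
                                            config$complexes$ligand[k]))
      prof <- stage("structure", contact_profile(cx, config$contact_cutoff))
      crows[[k]] <- data.frame(complex = basename(config$complexes$path[k]),
                               t(as.matrix(prof$counts)),
                               total = prof$total)
      prows[[k]] <- data.frame(complex = basename(config$complexes$path[k]),
                               delta_g = predict_affinity(prof, model))
      cmp_id <- config$complexes$comparison_protein_id[k]
      if (!is.na(cmp_id)) {
        cmp_seq <- meta$sequence[match(cmp_id, meta$protein_id)]
        if (is.na(cmp_seq))
          stop("stage 'structure' failed: comparison protein ", cmp_id,
               " not in metaproteome")
        pk <- stage("structure",
                    compare_pockets(cx, cmp_seq,
                                    pocket_cutoff = config$pocket_cutoff))
        pkrows[[k]] <- cbind(complex = basename(config$complexes$path[k]),
                             pk$residues,
                             n_insertions = pk$n_insertions)
      }
    }
    # Table 1 column order for the contact classes
    contact_df <- do.call(rbind, crows)
    tab1 <- c("CC", "CO", "CN", "CX", "OO", "OX", "NO", "NN", "NX", "XX")
    contact_df <- contact_df[c("complex", tab1, "total")]
    out(contact_df, "contacts.tsv")
    out(do.call(rbind, prows), "affinity.tsv")
    if (length(pkrows)) out(do.call(rbind, pkrows), "pocket_comparison.tsv")
    structure_res <- list(contacts = contact_df,
                          affinity = do.call(rbind, prows))
  }

  inputs <- unlist(list(config$targets_fasta, config$targets_meta,
                        config$meta_fasta, config$meta_annot,
                        config$pathogen_catalog, config$side_effects,
                        config$links,
                        if (!is.null(config$complexes))
                          config$complexes$path))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("metaprom")),
                   config_hash = hash,
                   config = {
                     x <- unclass(config)
                     x$output_dir <- NULL  # not part of the analysis
                     x$meta_fasta <- as.list(x$meta_fasta)
                     x$meta_annot <- as.list(x$meta_annot)
                     if (!is.null(x$complexes))
                       x$complexes <- as.list(x$complexes)
                     x
                   },
                   input_md5 = as.list(tools::md5sum(inputs)),
                   stage_counts = counts)
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(targets = targets, metaproteome = meta, hits = hits,
                 summary = summ, overlap = ov, phylum = pc_tab,
                 pathogenicity = patho, clinical = clinical,
                 structure = structure_res, manifest = manifest))
}
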