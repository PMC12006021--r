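# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# BLOSUM62 background residue frequencies (Robinson & Robinson), the null
# model consistent with the default scoring scheme.
BLOSUM62_BG <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
                 Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
                 L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
                 S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)

#' Random background protein sequences
#'
#' Residues drawn i.i.d. from the BLOSUM62 background frequencies.
#'
#' @param n number of sequences.
#' @param length_range integer range of sequence lengths (inclusive).
#' @param seed RNG seed.
#' @return Character vector of sequences.
#' @export
random_proteins <- function(n, length_range = c(120, 300), seed = NULL) {
  gen <- function() {
    # sample.int avoids the sample() scalar pitfall when min == max
    lens <- length_range[1L] - 1L +
      sample.int(length_range[2L] - length_range[1L] + 1L, n,
                 replace = TRUE)
    vapply(lens, function(L)
      paste(sample(names(BLOSUM62_BG), L, replace = TRUE,
                   prob = BLOSUM62_BG), collapse = ""), "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Mutate a sequence to a planted percent identity
#'
#' Substitution-only mutation: exactly `round((1 - t/100) * L)` positions
#' are replaced, each by a uniformly drawn *different* residue, so the
#' ungapped identity to the original is the planted value up to rounding.
#' The planted identity is part of the generator's contract, so each draw
#' is verified: if the substitutions happen to admit a gapped global
#' alignment (default scheme) whose identity deviates from the ungapped
#' value, the substitution set is redrawn. Output is still a
#' deterministic function of the seed.
#'
#' @param sequence amino-acid string of length >= 20.
#' @param target_identity planted identity in (0, 100].
#' @param seed RNG seed (same seed, same output).
#' @param max_tries redraw budget for the verification step.
#' @return The mutated sequence.
#' @export
mutate_to_identity <- function(sequence, target_identity, seed = NULL,
                               max_tries = 200L) {
  L <- nchar(sequence)
  if (L < 20L) stop("sequence too short to plant identity (length < 20)")
  if (!(target_identity > 0 && target_identity <= 100))
    stop("target_identity must be in (0, 100]")
  k <- round((1 - target_identity / 100) * L)
  if (k == 0L) return(sequence)
  realized <- 100 * (L - k) / L
  scheme <- scoring_scheme()
  gen <- function() {
    for (try in seq_len(max_tries)) {
      chars <- strsplit(sequence, "")[[1L]]
      pos <- sample(L, k)
      for (p in pos) {
        alt <- setdiff(AA20, chars[p])
        chars[p] <- alt[sample.int(length(alt), 1L)]
      }
      mut <- paste(chars, collapse = "")
      pid <- global_align(sequence, mut, scheme)$percent_identity
      if (abs(pid - realized) < 1e-9) return(mut)
    }
    stop("could not realise a ", target_identity,
         "% identity plant in ", max_tries, " draws")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Build a GTDB-style lineage string for a synthetic species
make_lineage <- function(phylum, species) {
  genus <- if (is.na(species)) NA else strsplit(species, " ")[[1L]][1L]
  parts <- c(d__ = "Bacteria", p__ = phylum, c__ = "SynClass",
             o__ = "SynOrder", f__ = "SynFamily", g__ = genus,
             s__ = species)
  keep <- !is.na(parts)
  paste0(names(parts)[keep], parts[keep], collapse = ";")
}

#' Generate a synthetic metaproteome with planted structure
#'
#' Emulates per-biome MAG catalogues: background proteins are drawn from
#' the BLOSUM62 background model (no similarity to the targets above
#' chance), planted homologs are derived from target sequences via
#' [mutate_to_identity()], and MAG species are assigned so that the
#' three-biome species overlap realises a specified Venn structure.
#' Planted homologs copy the target's function label when concordant,
#' otherwise they are annotated `"hypothetical protein"`.
#'
#' @param targets data.frame of target records.
#' @param plants data.frame with columns `target_id`, `biome`, `identity`
#'   and optional `concordant` (logical, default TRUE); `identity = 100`
#'   plants an exact duplicate. `NULL` = no plants.
#' @param n_background background proteins per biome.
#' @param venn named list/vector of species counts per Venn region:
#'   `all_three`, `gut_oral`, `gut_vaginal`, `oral_vaginal`, `gut_only`,
#'   `oral_only`, `vaginal_only`.
#' @param phylum_pool phylum names sampled for MAG lineages.
#' @param na_species_fraction fraction of MAGs whose lineage is truncated
#'   at genus level (species `NA`).
#' @param length_range background sequence length range.
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   it.
#' @return A list with `proteins` (annotation data.frame joined with
#'   sequences, as from [read_annotation_table()]) and `truth` (planted
#'   parameters: `plants` with realised protein ids, `venn`,
#'   `species_by_biome`, `seed`).
#' @export
generate_metaproteome <- function(targets, plants = NULL,
                                  n_background = 200,
                                  venn = c(all_three = 5, gut_oral = 3,
                                           gut_vaginal = 2,
                                           oral_vaginal = 2, gut_only = 10,
                                           oral_only = 8, vaginal_only = 6),
                                  phylum_pool = c("Firmicutes",
                                                  "Bacteroidota",
                                                  "Proteobacteria",
                                                  "Actinobacteriota"),
                                  na_species_fraction = 0.05,
                                  length_range = c(120, 300), seed = 1) {
  venn <- as.list(venn)
  need <- c("all_three", "gut_oral", "gut_vaginal", "oral_vaginal",
            "gut_only", "oral_only", "vaginal_only")
  miss <- setdiff(need, names(venn))
  if (length(miss))
    stop("venn spec lacks region(s): ", paste(miss, collapse = ", "))
  if (any(unlist(venn[need]) < 0)) stop("inconsistent venn spec")
  if (!is.null(plants)) {
    if (!all(plants$biome %in% BIOMES)) stop("unknown biome in plants")
    if (!all(plants$target_id %in% targets$target_id))
      stop("plant target_id not in targets")
    if (is.null(plants$concordant)) plants$concordant <- TRUE
    plants$protein_id <- NA_character_
  }
  with_seed(seed, {
    # species pools realising the requested Venn structure
    total_sp <- sum(unlist(venn[need]))
    sp_names <- sprintf("Synthospecies sp%03d", seq_len(max(total_sp, 1L)))
    take <- function(n) {
      out <- sp_names[seq_len(n)]
      sp_names <<- sp_names[-seq_len(n)]
      out
    }
    s_abc <- take(venn$all_three)
    s_go <- take(venn$gut_oral); s_gv <- take(venn$gut_vaginal)
    s_ov <- take(venn$oral_vaginal)
    s_g <- take(venn$gut_only); s_o <- take(venn$oral_only)
    s_v <- take(venn$vaginal_only)
    species_by_biome <- list(
      gut = c(s_abc, s_go, s_gv, s_g),
      oral = c(s_abc, s_go, s_ov, s_o),
      vaginal = c(s_abc, s_gv, s_ov, s_v))

    rows <- list()
    for (b in BIOMES) {
      sp <- species_by_biome[[b]]
      if (!length(sp)) sp <- NA_character_
      n_pl <- if (is.null(plants)) 0L else sum(plants$biome == b)
      n_tot <- n_background + n_pl
      if (n_tot < length(sp))
        warning("biome ", b, ": fewer proteins than pool species; ",
                "the planted Venn structure will not be fully realised")
      # one MAG per protein keeps species coverage simple and guarantees
      # every pool species appears at least once
      mag_sp <- c(rep_len(sp, min(n_tot, length(sp))),
                  if (n_tot > length(sp))
                    sample(sp, n_tot - length(sp), replace = TRUE))
      mag_sp <- sample(mag_sp)  # shuffle which proteins carry which species
      na_mag <- runif(n_tot) < na_species_fraction &
        duplicated(mag_sp)  # never blank a species' only MAG
      mag_sp[na_mag] <- NA
      phyla <- sample(phylum_pool, n_tot, replace = TRUE)
      seqs <- random_proteins(n_tot, length_range)
      fun <- sprintf("background function %d", sample(50L, n_tot,
                                                      replace = TRUE))
      pid <- sprintf("%s_prot_%05d", b, seq_len(n_tot))
      df <- data.frame(protein_id = pid, sequence = seqs,
                       mag_id = sprintf("%s_mag_%05d", b, seq_len(n_tot)),
                       biome = b, species = mag_sp, phylum = phyla,
                       function_annotation = fun, stringsAsFactors = FALSE)
      # overwrite the tail with plants
      if (n_pl > 0L) {
        pl_rows <- which(plants$biome == b)
        idx <- seq.int(n_background + 1L, n_tot)
        for (k in seq_along(pl_rows)) {
          r <- pl_rows[k]
          tgt <- targets[targets$target_id == plants$target_id[r], ]
          s <- if (plants$identity[r] >= 100) tgt$sequence
            else mutate_to_identity(tgt$sequence, plants$identity[r],
                                    seed = sample.int(2^31 - 1L, 1L))
          df$sequence[idx[k]] <- s
          df$function_annotation[idx[k]] <-
            if (isTRUE(plants$concordant[r])) tgt$function_label
            else "hypothetical protein"
          plants$protein_id[r] <- df$protein_id[idx[k]]
        }
      }
      df$lineage <- mapply(make_lineage, df$phylum, df$species,
                           USE.NAMES = FALSE)
      rows[[b]] <- df
    }
    proteins <- do.call(rbind, rows)
    rownames(proteins) <- NULL
    cols <- c("protein_id", "sequence", "mag_id", "biome", "lineage",
              "species", "phylum", "function_annotation")
    list(proteins = proteins[cols],
         truth = list(plants = plants, venn = venn,
                      species_by_biome = species_by_biome, seed = seed))
  })
}

#' Generate a synthetic drug side-effect dataset
#'
#' Emulates a SIDER-style flat file: each drug-symptom pair is an
#' independent Bernoulli draw with a per-group prevalence, and group
#' membership is realised through drug-target links (each affecting drug
#' links to a microbiome-affecting target and vice versa) so that
#' [assign_groups()] reconstructs the planted grouping.
#'
#' @param symptom_spec data.frame with columns `symptom`, `soc`,
#'   `p_affecting`, `p_non_affecting` (Bernoulli prevalences in \[0, 1\]).
#' @param affecting_targets,non_affecting_targets target ids to which the
#'   drugs of each group are linked (recycled over drugs).
#' @param n_drugs_per_group drugs per group.
#' @param seed RNG seed.
#' @return A list with `side_effects` (drug_id, symptom, soc), `links`
#'   (drug_id, target_id) and `truth` (the spec plus group memberships and
#'   seed).
#' @export
generate_side_effects <- function(symptom_spec, affecting_targets,
                                  non_affecting_targets,
                                  n_drugs_per_group = 100, seed = 1) {
  need <- c("symptom", "soc", "p_affecting", "p_non_affecting")
  miss <- setdiff(need, names(symptom_spec))
  if (length(miss))
    stop("symptom_spec lacks column(s): ", paste(miss, collapse = ", "))
  pr <- c(symptom_spec$p_affecting, symptom_spec$p_non_affecting)
  if (any(pr < 0 | pr > 1)) stop("prevalence outside [0, 1]")
  with_seed(seed, {
    drugs_a <- sprintf("DRUG_A%04d", seq_len(n_drugs_per_group))
    drugs_n <- sprintf("DRUG_N%04d", seq_len(n_drugs_per_group))
    links <- rbind(
      data.frame(drug_id = drugs_a,
                 target_id = rep_len(affecting_targets, n_drugs_per_group),
                 stringsAsFactors = FALSE),
      data.frame(drug_id = drugs_n,
                 target_id = rep_len(non_affecting_targets,
                                     n_drugs_per_group),
                 stringsAsFactors = FALSE))
    draw <- function(drugs, p) {
      rows <- lapply(seq_len(nrow(symptom_spec)), function(k) {
        on <- rbinom(length(drugs), 1L, p[k]) == 1L
        if (!any(on)) return(NULL)
        data.frame(drug_id = drugs[on], symptom = symptom_spec$symptom[k],
                   soc = symptom_spec$soc[k], stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    se <- rbind(draw(drugs_a, symptom_spec$p_affecting),
                draw(drugs_n, symptom_spec$p_non_affecting))
    if (is.null(se))
      se <- data.frame(drug_id = character(0), symptom = character(0),
                       soc = character(0), stringsAsFactors = FALSE)
    se <- se[order(se$drug_id, se$symptom), , drop = FALSE]
    rownames(se) <- NULL
    list(side_effects = se, links = links,
         truth = list(symptom_spec = symptom_spec,
                      affecting_drugs = drugs_a,
                      non_affecting_drugs = drugs_n, seed = seed))
  })
}

# evenly spread unit vectors (golden-spiral points on the sphere)
sphere_directions <- function(n) {
  k <- seq_len(n)
  phi <- acos(1 - 2 * (k - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * (k - 0.5)
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a synthetic posed protein-ligand complex
#'
#' Toy geometry with exact planted structure: the ligand is a single
#' carbon atom at the origin; pocket residues place their C-alpha at
#' `pocket_distance` from the ligand (each a CC contact by construction),
#' extra planted contacts are dedicated side-chain atoms of the requested
#' element placed inside the contact cutoff, and all remaining residues
#' sit on a ring far outside it. The returned truth records the realised
#' contact counts and pocket membership, recomputable by brute force.
#'
#' @param n_residues protein length (>= 2).
#' @param pocket_spec list with `pocket_residues` (residue numbers inside
#'   the pocket), `pocket_distance` (A, default 4.0) and optionally
#'   `contacts` (named counts of extra planted contacts per class, e.g.
#'   `c(CO = 2)`; only classes pairing with the ligand's carbon -- CC, CN,
#'   CO, CX -- can be planted).
#' @param contact_cutoff cutoff the truth counts refer to (default 10.5).
#' @param far_distance radius of the non-pocket ring (must exceed the
#'   cutoff).
#' @param seed RNG seed (residue identities).
#' @return A list with `complex` (a [complex_structure()]) and `truth`
#'   (`pocket_residues`, `contact_counts`, `sequence`, `seed`).
#' @export
generate_complex <- function(n_residues = 10,
                             pocket_spec = list(pocket_residues = integer(0),
                                                pocket_distance = 4.0),
                             contact_cutoff = 10.5, far_distance = 60,
                             seed = 1) {
  pocket <- as.integer(pocket_spec$pocket_residues %||% integer(0))
  pd <- pocket_spec$pocket_distance %||% 4.0
  extra <- pocket_spec$contacts %||% c()
  if (length(pocket) && (pd <= 0 || pd > contact_cutoff))
    stop("impossible geometry: pocket_distance outside (0, cutoff]")
  if (far_distance <= contact_cutoff)
    stop("impossible geometry: far_distance inside the contact cutoff")
  if (length(pocket) && any(pocket < 1L | pocket > n_residues))
    stop("pocket residue numbers outside 1..n_residues")
  bad <- setdiff(names(extra), c("CC", "CN", "CO", "CX"))
  if (length(bad))
    stop("cannot plant classes not pairing with the ligand carbon: ",
         paste(bad, collapse = ", "))
  with_seed(seed, {
    aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
    resnames <- sample(aa3, n_residues, replace = TRUE)
    dirs <- sphere_directions(n_residues + sum(extra) + 8L)
    rows <- list()
    di <- 1L
    for (r in seq_len(n_residues)) {
      d <- if (r %in% pocket) pd else far_distance
      xyz <- dirs[di, ] * d; di <- di + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        entity = "protein", element = "C", atom_name = "CA",
        resname = resnames[r], resno = r, chain = "A",
        x = xyz[1L], y = xyz[2L], z = xyz[3L], stringsAsFactors = FALSE)
    }
    # extra planted contacts: dedicated side-chain atoms on a pocket (or
    # first) residue, inside the cutoff
    host <- if (length(pocket)) pocket[1L] else 1L
    el_of <- c(CC = "C", CN = "N", CO = "O", CX = "S")
    for (cl in names(extra)) {
      for (k in seq_len(extra[[cl]])) {
        xyz <- dirs[di, ] * (contact_cutoff - 1.5); di <- di + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          entity = "protein", element = el_of[[cl]],
          atom_name = paste0(el_of[[cl]], "B"),
          resname = resnames[host], resno = host, chain = "A",
          x = xyz[1L], y = xyz[2L], z = xyz[3L], stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      entity = "ligand", element = "C", atom_name = "C1", resname = "LIG",
      resno = 900L, chain = "L", x = 0, y = 0, z = 0,
      stringsAsFactors = FALSE)
    cx <- complex_structure(do.call(rbind, rows), "LIG")
    counts <- setNames(integer(length(CONTACT_CLASSES)), CONTACT_CLASSES)
    counts["CC"] <- length(pocket)
    for (cl in names(extra)) counts[cl] <- counts[cl] + extra[[cl]]
    one <- setNames(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]], aa3)
    list(complex = cx,
         truth = list(pocket_residues = pocket, contact_counts = counts,
                      sequence = paste(one[resnames], collapse = ""),
                      seed = seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate and write a complete synthetic study dataset
#'
#' Writes every input the pipeline reads -- target FASTA + metadata,
#' per-biome metaproteome FASTA + annotation TSVs, pathogen catalog CSV,
#' side-effect and drug-target-link TSVs, one posed complex PDB -- plus a
#' `truth.json` with the planted parameters. The defaults define the
#' package's reference study conditions: 20 targets (10 human, 10
#' pathogen), 200 metaproteome proteins per biome with planted homologs at
#' 20-100% identity, 100 drugs per group with a planted infection-symptom
#' enrichment (0.6 vs 0.2).
#'
#' @param dir output directory (created if needed).
#' @param n_targets total targets (half human, half pathogen).
#' @param n_background background metaproteome proteins per biome.
#' @param n_drugs_per_group drugs per clinical group.
#' @param seed master seed; every file is a deterministic function of it.
#' @return A list with `paths` (named file paths) and `truth`.
#' @export
synthetic_dataset <- function(dir, n_targets = 20, n_background = 200,
                              n_drugs_per_group = 100, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_h <- ceiling(n_targets / 2); n_p <- n_targets - n_h
  with_seed(seed + 1L, {
    fn_pool <- c("dihydrofolate reductase", "acetylcholinesterase",
                 "carbonic anhydrase 2", "peptidyl-prolyl cis-trans isomerase",
                 "DNA-directed RNA polymerase", "beta-lactamase",
                 "DNA gyrase", "ATP synthase", "penicillin-binding protein",
                 "sodium/glucose cotransporter 2")
    targets <- data.frame(
      target_id = sprintf("T%03d", seq_len(n_targets)),
      sequence = random_proteins(n_targets, c(150, 250)),
      target_organism = c(rep("Homo sapiens", n_h),
                          sample(c("Escherichia coli",
                                   "Mycobacterium tuberculosis",
                                   "Staphylococcus aureus"), n_p,
                                 replace = TRUE)),
      target_class = c(rep("human", n_h), rep("pathogen", n_p)),
      function_label = rep_len(fn_pool, n_targets),
      drug_ids = "", stringsAsFactors = FALSE)
  })

  # planted homologs: a ladder of identities across biomes, plus exact
  # duplicates of pathogen targets (the identical-match signal)
  path_ids <- targets$target_id[targets$target_class == "pathogen"]
  hum_ids <- targets$target_id[targets$target_class == "human"]
  # human plants: an identity ladder (the 20% plant must never be called);
  # pathogen plants: a near-identical homolog plus exact duplicates per
  # biome (the identical-match signal). Ladders shrink with small target
  # sets.
  hum_spec <- data.frame(biome = c("gut", "gut", "oral", "vaginal", "gut"),
                         identity = c(35, 50, 65, 80, 20),
                         concordant = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  kh <- min(length(hum_ids), nrow(hum_spec))
  path_spec <- data.frame(idx = c(1L, 1L, 2L, 3L),
                          biome = c("gut", "gut", "oral", "vaginal"),
                          identity = c(95, 100, 100, 100))
  path_spec <- path_spec[path_spec$idx <= length(path_ids), , drop = FALSE]
  plants <- rbind(
    data.frame(target_id = hum_ids[seq_len(kh)],
               biome = hum_spec$biome[seq_len(kh)],
               identity = hum_spec$identity[seq_len(kh)],
               concordant = hum_spec$concordant[seq_len(kh)],
               stringsAsFactors = FALSE),
    data.frame(target_id = path_ids[path_spec$idx],
               biome = path_spec$biome, identity = path_spec$identity,
               concordant = TRUE, stringsAsFactors = FALSE))
  ms <- generate_metaproteome(targets, plants, n_background = n_background,
                              seed = seed + 2L)

  # pathogen catalog: half of the all-three + gut-only species
  sp_pool <- unique(unlist(ms$truth$species_by_biome))
  catalog <- with_seed(seed + 3L,
                       sample(sp_pool, max(1L, length(sp_pool) %/% 3L)))

  symptom_spec <- data.frame(
    symptom = c("planted infection", "planted anaemia", "planted rash",
                sprintf("background symptom %02d", 1:12)),
    soc = c("Infections and infestations",
            "Blood and lymphatic system disorders",
            "Skin and subcutaneous tissue disorders",
            rep_len(c("Gastrointestinal disorders", "Cardiac disorders",
                      "Nervous system disorders", "Psychiatric disorders"),
                    12L)),
    p_affecting = c(0.6, 0.5, 0.3, rep_len(c(0.3, 0.2, 0.25, 0.15), 12L)),
    p_non_affecting = c(0.2, 0.25, 0.3, rep_len(c(0.3, 0.2, 0.25, 0.15),
                                                12L)),
    stringsAsFactors = FALSE)
  affecting <- unique(plants$target_id[plants$identity > 30])
  non_affecting <- setdiff(targets$target_id, unique(plants$target_id))
  se <- generate_side_effects(symptom_spec, affecting, non_affecting,
                              n_drugs_per_group = n_drugs_per_group,
                              seed = seed + 4L)

  cxg <- generate_complex(n_residues = 12,
                          pocket_spec = list(pocket_residues = c(5L, 6L, 7L),
                                             pocket_distance = 4.0,
                                             contacts = c(CO = 2L, CN = 1L)),
                          seed = seed + 5L)

  paths <- list(
    targets_fasta = file.path(dir, "targets.fasta"),
    targets_meta = file.path(dir, "targets.tsv"),
    meta_fasta = setNames(file.path(dir, paste0("meta_", BIOMES, ".fasta")),
                          BIOMES),
    meta_annot = setNames(file.path(dir, paste0("meta_", BIOMES, ".tsv")),
                          BIOMES),
    pathogen_catalog = file.path(dir, "pathogen_catalog.csv"),
    side_effects = file.path(dir, "side_effects.tsv"),
    links = file.path(dir, "drug_targets.tsv"),
    complex_pdb = file.path(dir, "complex_synthetic.pdb"),
    truth = file.path(dir, "truth.json"))

  write_fasta(data.frame(id = targets$target_id,
                         sequence = targets$sequence), paths$targets_fasta)
  write.table(targets[c("target_id", "target_organism", "target_class",
                        "function_label", "drug_ids")],
              paths$targets_meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (b in BIOMES) {
    sub <- ms$proteins[ms$proteins$biome == b, , drop = FALSE]
    write_fasta(data.frame(id = sub$protein_id, sequence = sub$sequence),
                paths$meta_fasta[[b]])
    ann <- data.frame(protein_id = sub$protein_id, mag_id = sub$mag_id,
                      biome = sub$biome, lineage = sub$lineage,
                      "function" = sub$function_annotation,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(ann, paths$meta_annot[[b]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  writeLines(c("species", catalog), paths$pathogen_catalog)
  write.table(se$side_effects, paths$side_effects, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(se$links, paths$links, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_complex(cxg$complex, paths$complex_pdb)

  truth <- list(seed = seed, plants = ms$truth$plants,
                venn = ms$truth$venn,
                species_by_biome = ms$truth$species_by_biome,
                pathogen_catalog = catalog,
                symptom_spec = symptom_spec,
                affecting_targets = affecting,
                complex = cxg$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(paths = paths, truth = truth)
}
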