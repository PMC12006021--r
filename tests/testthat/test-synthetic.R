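test_that("identity planting is exact and deterministic", {
  base <- random_proteins(1, c(100, 100), seed = 12)
  expect_identical(mutate_to_identity(base, 100, seed = 1), base)
  m50a <- mutate_to_identity(base, 50, seed = 2)
  m50b <- mutate_to_identity(base, 50, seed = 2)
  expect_identical(m50a, m50b)
  expect_false(identical(m50a, mutate_to_identity(base, 50, seed = 3)))
  # exactly 50 of 100 positions differ, and global identity is 50.0
  diffs <- sum(strsplit(base, "")[[1]] != strsplit(m50a, "")[[1]])
  expect_equal(diffs, 50L)
  expect_equal(global_align(base, m50a)$percent_identity, 50)
  expect_error(mutate_to_identity("SHORTSEQ", 50), "short")
  expect_error(mutate_to_identity(base, 0), "0, 100")
})

test_that("generated metaproteomes realise the planted structure", {
  tg <- toy_targets(c("T1", "T2"), random_proteins(2, c(150, 200), seed = 1))
  plants <- data.frame(target_id = c("T1", "T1", "T2"),
                       biome = c("gut", "oral", "gut"),
                       identity = c(20, 35, 50))
  ms <- generate_metaproteome(tg, plants, n_background = 60, seed = 4)
  expect_equal(nrow(ms$proteins), 3 * 60 + 3)
  # plants carry realised protein ids and the planted identity
  tr <- ms$truth$plants
  for (k in seq_len(nrow(tr))) {
    planted <- ms$proteins$sequence[ms$proteins$protein_id ==
                                      tr$protein_id[k]]
    tgt <- tg$sequence[tg$target_id == tr$target_id[k]]
    expect_equal(global_align(tgt, planted)$percent_identity,
                 tr$identity[k], tolerance = 1)
  }
  # threshold semantics on the planted truth: only the 35 and 50 plants
  hits <- screen_targets(tg, ms$proteins)
  expect_setequal(hits$protein_id,
                  tr$protein_id[tr$identity > 30])
  # determinism: same seed, same data
  ms2 <- generate_metaproteome(tg, plants, n_background = 60, seed = 4)
  expect_identical(ms$proteins, ms2$proteins)
})

test_that("background metaproteomes yield no off-target calls", {
  # target seed disjoint from the metaproteome seeds: seeding two
  # generators identically would replay the same residue stream
  tg <- toy_targets(c("T1", "T2", "T3"),
                    random_proteins(3, c(150, 250), seed = 1000))
  for (seed in 1:5) {
    ms <- generate_metaproteome(tg, plants = NULL, n_background = 40,
                                seed = seed)
    hits <- screen_targets(tg, ms$proteins)
    expect_equal(nrow(hits), 0L, info = seed)
  }
})

test_that("side-effect generation respects the planted prevalences", {
  spec <- data.frame(symptom = c("always", "aff_only"),
                     soc = "General disorders",
                     p_affecting = c(1, 0.5), p_non_affecting = c(1, 0))
  g <- generate_side_effects(spec, "TA", "TN", n_drugs_per_group = 10,
                             seed = 3)
  # deterministic under the seed
  g2 <- generate_side_effects(spec, "TA", "TN", n_drugs_per_group = 10,
                              seed = 3)
  expect_identical(g$side_effects, g2$side_effects)
  # p = 1 in both groups: shared with zero percent change
  tg <- toy_targets(c("TA", "TN"), random_proteins(2, c(30, 30), seed = 5))
  a <- assign_groups(tg, toy_hits("TA", "p1"), g$links)
  shared <- attr(prevalence_change(a, g$side_effects, min_change = 0),
                 "shared_all")
  expect_equal(shared$percent_change[shared$symptom == "always"], 0)
  # p = (0.5, 0): unique to the affecting group when it occurs at all
  p <- symptom_partition(a, g$side_effects)
  if ("aff_only" %in% p$table$symptom)
    expect_true("aff_only" %in% p$unique_affecting)
  expect_error(generate_side_effects(
    data.frame(symptom = "s", soc = "x", p_affecting = 1.5,
               p_non_affecting = 0), "TA", "TN"), "0, 1")
})

test_that("synthetic complexes realise planted contacts exactly", {
  g <- generate_complex(n_residues = 8,
                        pocket_spec = list(pocket_residues = c(2L, 5L),
                                           pocket_distance = 4.0,
                                           contacts = c(CC = 2L, CO = 2L)),
                        seed = 6)
  p <- contact_profile(g$complex)
  expect_equal(p$counts, g$truth$contact_counts)
  expect_equal(p$counts[["CC"]], 4L)  # 2 pocket CAs + 2 planted
  expect_equal(p$counts[["CO"]], 2L)
  expect_equal(brute_contact_counts(g$complex, 10.5), p$counts)
  expect_error(generate_complex(
    pocket_spec = list(pocket_residues = 1L, pocket_distance = 50)),
    "impossible")
  expect_error(generate_complex(n_residues = 4, far_distance = 5),
    "impossible")
})

test_that("the full synthetic dataset reads back consistently", {
  dir <- tempfile("synth")
  d <- synthetic_dataset(dir, n_targets = 8, n_background = 40,
                         n_drugs_per_group = 20, seed = 11)
  tg <- read_targets(d$paths$targets_fasta, d$paths$targets_meta)
  expect_equal(nrow(tg), 8L)
  ann <- read_annotation_table(d$paths$meta_annot[["gut"]],
                               d$paths$meta_fasta[["gut"]])
  expect_true(all(ann$biome == "gut"))
  se <- read_side_effect_table(d$paths$side_effects)
  links <- read_drug_target_links(d$paths$links)
  expect_setequal(unique(se$drug_id) %in% links$drug_id, TRUE)
  cat <- read_pathogen_catalog(d$paths$pathogen_catalog)
  expect_gt(length(cat), 0L)
  truth <- jsonlite::read_json(d$paths$truth)
  expect_equal(truth$seed, 11L)
})
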