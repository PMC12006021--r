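base200 <- random_proteins(1, c(200, 200), seed = 31)

test_that("screening calls planted homologs and only them", {
  tg <- toy_targets("T1", base200)
  meta <- toy_metaproteome(
    c("p_ident", "p_half", "p_thirty", "p_noise"),
    c(base200,
      mutate_to_identity(base200, 50, seed = 1),
      mutate_to_identity(base200, 30, seed = 2),
      random_proteins(1, c(200, 200), seed = 99)))
  hits <- screen_targets(tg, meta)
  expect_s3_class(hits, "offtarget_hits")
  expect_setequal(hits$protein_id, c("p_ident", "p_half"))
  expect_true(hits$is_identical[hits$protein_id == "p_ident"])
  expect_false(hits$is_identical[hits$protein_id == "p_half"])
  expect_equal(hits$percent_identity[hits$protein_id == "p_ident"], 100)
  expect_equal(hits$percent_identity[hits$protein_id == "p_half"], 50,
               tolerance = 0.02)
  # 30.0% plant: "above 30%" is strict, so it is NOT emitted
  expect_false("p_thirty" %in% hits$protein_id)
})

test_that("raising the threshold never adds hits and counts conserve", {
  tg <- toy_targets(c("T1", "T2"),
                    c(base200, random_proteins(1, c(180, 180), seed = 5)))
  meta <- toy_metaproteome(
    paste0("p", 1:4),
    c(mutate_to_identity(base200, 40, seed = 3),
      mutate_to_identity(base200, 60, seed = 4),
      mutate_to_identity(base200, 90, seed = 5),
      base200),
    biome = c("gut", "oral", "gut", "vaginal"))
  lo <- screen_targets(tg, meta, similarity_threshold = 30)
  hi <- screen_targets(tg, meta, similarity_threshold = 55)
  key <- function(h) paste(h$target_id, h$protein_id)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
  # per-biome counts sum to the total
  expect_equal(sum(table(lo$biome)), nrow(lo))
  # deterministic output order
  expect_equal(order(lo$target_id, lo$protein_id), seq_len(nrow(lo)))
  expect_error(screen_targets(tg, meta, similarity_threshold = 0),
               "0, 100")
})

test_that("identical matches count unique proteins once", {
  s <- random_proteins(1, c(150, 150), seed = 8)
  tg <- toy_targets(c("P1", "P2"), c(s, s), class = "pathogen")
  meta <- toy_metaproteome("dup1", s, biome = "oral")
  hits <- screen_targets(tg, meta)
  expect_equal(sum(hits$is_identical), 2L)  # one protein, two targets
  im <- identical_matches(hits)
  expect_equal(nrow(im), 6L)  # full biome x class grid
  expect_equal(im$n_identical_proteins[im$biome == "oral" &
                                         im$target_class == "pathogen"], 1L)
  expect_true(all(im$n_identical_proteins[im$biome != "oral"] == 0L))
  # no identical hits at all -> all-zero grid
  h2 <- hits; h2$is_identical <- FALSE
  expect_true(all(identical_matches(h2)$n_identical_proteins == 0L))
})

test_that("function concordance applies the strict 50% cutoff", {
  hits <- toy_hits(
    target_id = "T1", protein_id = paste0("p", 1:6),
    percent_identity = c(80, 70, 60, 55, 52, 50),
    function_label = "dihydrofolate reductase",
    function_annotation = c(rep("dihydrofolate reductase", 3),
                            "hypothetical protein", "hypothetical protein",
                            "dihydrofolate reductase"))
  fc <- function_concordance(hits)
  expect_equal(sum(fc$n), 5L)  # the 50.0% hit is excluded (strict)
  expect_equal(fc$n[fc$concordance == "identical function"], 3L)
  # target function mapping onto hypothetical proteins is retained
  hyp <- fc[fc$function_annotation == "hypothetical protein", ]
  expect_equal(hyp$n, 2L)
  expect_equal(hyp$concordance, "other")
  # nothing above the cutoff -> empty table
  low <- toy_hits("T1", "p1", percent_identity = 45)
  expect_equal(nrow(function_concordance(low)), 0L)
})

test_that("screen summaries aggregate the stored hits", {
  hits <- toy_hits(target_id = c("T1", "T1", "T2"),
                   protein_id = c("p1", "p2", "p3"),
                   biome = c("gut", "gut", "oral"),
                   percent_identity = c(40, 60, 80),
                   species = c("a b", "c d", "a b"))
  s <- screen_summary(hits)
  gut <- s$by_group[s$by_group$biome == "gut", ]
  expect_equal(gut$n_hits, 2L)
  expect_equal(gut$mean_identity, 50)
  expect_equal(s$by_target$n_hits[s$by_target$target_id == "T1"], 2L)
  expect_equal(s$by_target$n_species[s$by_target$target_id == "T1"], 2L)
})
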