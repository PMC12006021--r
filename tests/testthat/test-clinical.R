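# small helper: an assignment built from explicit drug groups
make_assignment <- function(n_affecting, n_non) {
  targets <- toy_targets(c("TA", "TN"),
                         random_proteins(2, c(30, 30), seed = 1))
  hits <- toy_hits("TA", "p1")
  links <- rbind(
    data.frame(drug_id = sprintf("A%03d", seq_len(n_affecting)),
               target_id = "TA"),
    data.frame(drug_id = sprintf("N%03d", seq_len(n_non)),
               target_id = "TN"))
  assign_groups(targets, hits, links)
}

se_row <- function(drug, symptom, soc = "General disorders")
  data.frame(drug_id = drug, symptom = symptom, soc = soc,
             stringsAsFactors = FALSE)

test_that("targets partition into affecting and non-affecting", {
  tg <- toy_targets(c("T1", "T2", "T3"),
                    random_proteins(3, c(30, 30), seed = 2))
  none <- toy_hits("T9", "p")[0, ]
  a0 <- assign_groups(tg, none)
  expect_true(all(a0$targets$group == "non_affecting"))
  all_hit <- toy_hits(c("T1", "T2", "T3"), c("p1", "p2", "p3"))
  a1 <- assign_groups(tg, all_hit)
  expect_true(all(a1$targets$group == "affecting"))
})

test_that("a drug with one affecting target is affecting", {
  tg <- toy_targets(c("T1", "T2"), random_proteins(2, c(30, 30), seed = 3))
  hits <- toy_hits("T1", "p1")
  links <- data.frame(drug_id = c("d1", "d1", "d2"),
                      target_id = c("T1", "T2", "T2"))
  a <- assign_groups(tg, hits, links)
  expect_equal(a$drugs$group[a$drugs$drug_id == "d1"], "affecting")
  expect_equal(a$drugs$group[a$drugs$drug_id == "d2"], "non_affecting")
  # unlinked target warns and is excluded from drug-level analysis
  tg3 <- rbind(tg, toy_targets("T3", random_proteins(1, c(30, 30),
                                                     seed = 4)))
  expect_warning(assign_groups(tg3, hits, links), "T3")
})

test_that("symptoms partition into unique and shared sets", {
  a <- make_assignment(2, 2)
  se <- rbind(se_row("A001", "s_uniqA1"), se_row("A002", "s_uniqA1"),
              se_row("A001", "s_uniqA2"),
              se_row("N001", "s_uniqN"),
              se_row("A001", "s_sh1"), se_row("N001", "s_sh1"),
              se_row("A002", "s_sh2"), se_row("N002", "s_sh2"),
              se_row("A001", "s_sh3"), se_row("N002", "s_sh3"),
              se_row("ZZZ", "ignored"))  # drug outside the assignment
  p <- symptom_partition(a, se)
  expect_setequal(p$unique_affecting, c("s_uniqA1", "s_uniqA2"))
  expect_equal(p$unique_non_affecting, "s_uniqN")
  expect_setequal(p$shared, c("s_sh1", "s_sh2", "s_sh3"))
  # conservation: the three sets cover every observed symptom
  expect_equal(length(p$unique_affecting) + length(p$unique_non_affecting) +
                 length(p$shared), nrow(p$table))
  expect_false("ignored" %in% p$table$symptom)
  # all drugs in one group -> everything unique to it
  se1 <- rbind(se_row("A001", "x"), se_row("A002", "y"))
  p1 <- symptom_partition(a, se1)
  expect_setequal(p1$unique_affecting, c("x", "y"))
  expect_error(symptom_partition(a, se1[0, ]), "empty")
})

test_that("percent change follows the hand computation", {
  a <- make_assignment(4, 4)
  se <- rbind(se_row(sprintf("A%03d", 1:4), "sym"),   # 4/4 affecting
              se_row(sprintf("N%03d", 1:2), "sym"),   # 2/4 non-affecting
              se_row("A001", "anchor"), se_row("N001", "anchor"))
  pc <- prevalence_change(a, se, min_change = 10)
  sym <- pc[pc$symptom == "sym", ]
  expect_equal(sym$p_affecting, 1.0)
  expect_equal(sym$p_non_affecting, 0.5)
  expect_equal(sym$percent_change, 100)
  # equal prevalence -> zero change, filtered out
  expect_false("anchor" %in% pc$symptom)
  # output sorted by |percent change| descending
  expect_equal(pc$percent_change, pc$percent_change[
    order(-abs(pc$percent_change))])
})

test_that("a change of exactly +10% is filtered (strict)", {
  a <- make_assignment(16, 16)
  se <- rbind(se_row(sprintf("A%03d", 1:11), "edge"),  # 11/16
              se_row(sprintf("N%03d", 1:10), "edge"))  # 10/16 -> +10.0%
  shared <- attr(prevalence_change(a, se, min_change = 0), "shared_all")
  expect_equal(shared$percent_change[shared$symptom == "edge"], 10)
  pc <- prevalence_change(a, se, min_change = 10)
  expect_false("edge" %in% pc$symptom)
})

test_that("swapping group labels inverts the change consistently", {
  a <- make_assignment(5, 8)
  # swapped assignment: relabel the groups
  b <- a
  b$drugs$group <- ifelse(a$drugs$group == "affecting", "non_affecting",
                          "affecting")
  b$targets$group <- ifelse(a$targets$group == "affecting",
                            "non_affecting", "affecting")
  set.seed(21)
  drugs <- a$drugs$drug_id
  se <- do.call(rbind, lapply(c("u", "v", "w"), function(s)
    se_row(sample(drugs, sample(3:10, 1)), s)))
  se <- unique(se)
  fwd <- attr(prevalence_change(a, se, min_change = 0), "shared_all")
  rev <- attr(prevalence_change(b, se, min_change = 0), "shared_all")
  shared <- intersect(fwd$symptom, rev$symptom)
  for (s in shared) {
    pc <- fwd$percent_change[fwd$symptom == s]
    pc_swapped <- rev$percent_change[rev$symptom == s]
    expect_equal(pc_swapped, 100 * (1 / (1 + pc / 100) - 1),
                 tolerance = 1e-12)
  }
  # swapping also swaps the unique sets
  p_f <- symptom_partition(a, se); p_r <- symptom_partition(b, se)
  expect_setequal(p_f$unique_affecting, p_r$unique_non_affecting)
})

test_that("permutation null attaches calibrated p-values", {
  a <- make_assignment(10, 10)
  se <- rbind(se_row(sprintf("A%03d", 1:9), "strong"),
              se_row("N001", "strong"),
              se_row(c("A001", "N002"), "weak"))
  pc <- prevalence_change(a, se, min_change = 0, n_perm = 200, seed = 5)
  expect_true("perm_p" %in% names(pc))
  expect_true(all(pc$perm_p > 0 & pc$perm_p <= 1))
  # the zero-change symptom is filtered, but keeps its p-value in the
  # unfiltered shared table
  shared <- attr(pc, "shared_all")
  expect_lt(shared$perm_p[shared$symptom == "strong"],
            shared$perm_p[shared$symptom == "weak"])
})

test_that("system-organ-class rollup counts both directions", {
  a <- make_assignment(10, 10)
  se <- rbind(se_row(sprintf("A%03d", 1:8), "up1", "Infections"),
              se_row("N001", "up1", "Infections"),
              se_row(sprintf("A%03d", 1:6), "up2", "Infections"),
              se_row("N002", "up2", "Infections"),
              se_row("A001", "down1", "Cardiac"),
              se_row(sprintf("N%03d", 1:7), "down1", "Cardiac"),
              se_row(c("A002", "N003"), "flat", "Infections"))
  roll <- soc_rollup(prevalence_change(a, se, min_change = 10))
  inf <- roll[roll$soc == "Infections", ]
  expect_equal(inf$n_up, 2L)
  expect_equal(inf$n_down, 0L)
  expect_equal(inf$n_shared, 3L)  # up1, up2, flat all shared Infections
  expect_equal(roll$n_down[roll$soc == "Cardiac"], 1L)
})
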