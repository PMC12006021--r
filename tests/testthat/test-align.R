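sc <- scoring_scheme()

test_that("self-alignment is 100% identical with no gaps", {
  for (s in c("MKV", "ACDEFGHIKLMNPQRSTVWY",
              random_proteins(2, c(30, 60), seed = 3))) {
    a <- global_align(s, s, sc)
    expect_equal(a$percent_identity, 100)
    expect_equal(a$n_columns, nchar(s))
    expect_false(grepl("-", a$aligned_query, fixed = TRUE))
    expect_equal(a$query_coverage, 1)
  }
})

test_that("hand-summed scores are reproduced", {
  # 4 x BLOSUM62(A,A) = 16
  expect_equal(global_align("AAAA", "AAAA", sc)$score, 16)
  # one mismatch column: 3*4 + BLOSUM62(A,R) = 12 - 1
  expect_equal(global_align("AAAA", "AARA", sc)$score, 11)
})

test_that("both aligners match exhaustive enumeration on small pairs", {
  set.seed(42)
  alpha <- c("A", "R", "N", "W", "C", "G")
  for (k in 1:40) {
    q <- paste(sample(alpha, sample(1:5, 1), TRUE), collapse = "")
    s <- paste(sample(alpha, sample(1:5, 1), TRUE), collapse = "")
    g <- global_align(q, s, sc)
    l <- local_align(q, s, sc)
    expect_equal(g$score, enum_global_score(q, s, sc), info = paste(q, s))
    expect_equal(l$score, enum_local_score(q, s, sc), info = paste(q, s))
    # relaxation: local never scores below global
    expect_gte(l$score, g$score)
    # symmetry of score and identity
    g2 <- global_align(s, q, sc)
    expect_equal(g2$score, g$score)
    expect_equal(g2$percent_identity, g$percent_identity)
    # the reported aligned strings re-score to the reported score
    expect_equal(rescore_alignment(g$aligned_query, g$aligned_subject, sc),
                 g$score)
    if (l$n_columns > 0)
      expect_equal(rescore_alignment(l$aligned_query, l$aligned_subject, sc),
                   l$score)
  }
})

test_that("alignment scores agree with an independent aligner", {
  # Biostrings charges open + extend*len per gap; ours charges
  # open + extend*(len-1), so gapOpening = open - extend matches
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(7)
  for (k in 1:20) {
    q <- random_proteins(1, c(10, 40))
    s <- random_proteins(1, c(10, 40))
    for (type in c("global", "local")) {
      ours <- if (type == "global") global_align(q, s, sc)
        else local_align(q, s, sc)
      ref <- Biostrings::pairwiseAlignment(
        q, s, substitutionMatrix = BLOSUM62,
        gapOpening = sc$gap_open - sc$gap_extend,
        gapExtension = sc$gap_extend, type = type, scoreOnly = TRUE)
      expect_equal(ours$score, if (type == "local") max(ref, 0) else ref,
                   info = type)
    }
  }
})

test_that("local alignment floors at zero for unrelated residues", {
  # all cross-residue BLOSUM62 entries between W and P are negative
  l <- local_align("WWWW", "PPPP", sc)
  expect_equal(l$score, 0)
  expect_equal(l$n_columns, 0)
  expect_equal(l$aligned_query, "")
  expect_equal(l$percent_identity, 0)
})

test_that("X scores zero and never counts as identical", {
  a <- global_align("XXXX", "XXXX", sc)
  expect_equal(a$score, 0)
  expect_equal(a$n_identical, 0)
  expect_equal(a$percent_identity, 0)
})

test_that("empty sequences are rejected", {
  expect_error(global_align("", "MKV"), "non-empty")
  expect_error(local_align("MKV", ""), "non-empty")
})

test_that("E-value follows the Karlin-Altschul closed form", {
  expect_equal(evalue(0, 100, 200, sc), sc$ka_K * 100 * 200)
  # linear in each length
  expect_equal(evalue(20, 100, 400, sc), 2 * evalue(20, 100, 200, sc))
  # independent evaluation of the closed form
  expect_equal(evalue(50, 100, 100, sc), 0.041 * 1e4 * exp(-13.35))
  # strictly decreasing in score
  ev <- evalue(0:60, 100, 100, sc)
  expect_true(all(diff(ev) < 0))
  expect_error(evalue(-1, 10, 10, sc), "non-negative")
  expect_error(evalue(5, 0, 10, sc), "positive")
})

test_that("batch scoring agrees with single-pair alignment", {
  qs <- random_proteins(5, c(8, 20), seed = 9)
  ss <- random_proteins(5, c(8, 20), seed = 10)
  expect_equal(align_scores(qs, ss, sc, "global"),
               mapply(function(q, s) global_align(q, s, sc)$score, qs, ss,
                      USE.NAMES = FALSE))
  expect_equal(align_scores(qs, ss, sc, "local"),
               mapply(function(q, s) local_align(q, s, sc)$score, qs, ss,
                      USE.NAMES = FALSE))
})
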