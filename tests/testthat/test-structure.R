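test_that("contact profiles match constructed geometries", {
  # ligand far outside the cutoff: empty profile
  far <- generate_complex(n_residues = 5, seed = 1)
  expect_equal(contact_profile(far$complex)$total, 0L)
  # one protein carbon 3 A from the ligand carbon: a single CC contact
  one <- complex_structure(
    data.frame(entity = c("protein", "ligand"), element = "C",
               atom_name = c("CA", "C1"), resname = c("ALA", "LIG"),
               resno = c(1L, 90L), chain = c("A", "L"),
               x = c(3, 0), y = 0, z = 0, stringsAsFactors = FALSE),
    "LIG")
  p <- contact_profile(one)
  expect_equal(p$counts[["CC"]], 1L)
  expect_equal(p$total, 1L)
})

test_that("contact counting equals the brute-force classifier", {
  for (seed in 1:10) {
    cx <- random_complex(seed)
    p <- contact_profile(cx, cutoff = 6)
    expect_equal(p$counts, brute_contact_counts(cx, 6), info = seed)
    expect_equal(p$total, sum(p$counts))
  }
})

test_that("contacts are invariant under rigid motion and monotone in cutoff", {
  cx <- random_complex(77)
  p0 <- contact_profile(cx, cutoff = 6)
  for (seed in 1:5) {
    moved <- apply_rigid(cx, random_rigid_transform(seed))
    expect_equal(contact_profile(moved, cutoff = 6)$counts, p0$counts)
  }
  totals <- vapply(c(2, 4, 6, 8, 10.5),
                   function(ct) contact_profile(cx, ct)$total, 0L)
  expect_true(all(diff(totals) >= 0))
})

test_that("hydrogens are excluded from contacts", {
  at <- data.frame(entity = c("protein", "protein", "ligand"),
                   element = c("C", "H", "C"),
                   atom_name = c("CA", "HA", "C1"),
                   resname = c("ALA", "ALA", "LIG"),
                   resno = c(1L, 1L, 90L), chain = c("A", "A", "L"),
                   x = c(3, 2, 0), y = 0, z = 0, stringsAsFactors = FALSE)
  p <- contact_profile(complex_structure(at, "LIG"))
  expect_equal(p$total, 1L)  # only the carbon pair
})

test_that("affinity prediction is exactly linear", {
  unit <- affinity_model(0, setNames(rep(1, 10),
                                     c("CC", "CN", "CO", "CX", "NN", "NO",
                                       "NX", "OO", "OX", "XX")))
  zero <- structure(list(counts = setNames(integer(10), names(unit$coefficients)),
                         total = 0L, cutoff_used = 10.5),
                    class = "contact_profile")
  model <- default_affinity_model()
  expect_equal(predict_affinity(zero, model), model$intercept)
  # unit coefficients: prediction = total contact count
  p17 <- zero
  p17$counts[c("CC", "CO", "NN")] <- c(10L, 5L, 2L)
  expect_equal(predict_affinity(p17, unit), 17)
  # superposition to machine precision
  set.seed(9)
  a <- zero; a$counts[] <- as.integer(sample(0:50, 10))
  b <- zero; b$counts[] <- as.integer(sample(0:50, 10))
  ab <- zero; ab$counts <- a$counts + b$counts
  expect_equal(predict_affinity(ab, model) - model$intercept,
               (predict_affinity(a, model) - model$intercept) +
                 (predict_affinity(b, model) - model$intercept),
               tolerance = 1e-12)
  # doubling every count doubles the excess over the intercept
  a2 <- zero; a2$counts <- 2L * a$counts
  expect_equal(predict_affinity(a2, model) - model$intercept,
               2 * (predict_affinity(a, model) - model$intercept))
  expect_error(affinity_model(0, c(CC = 1)), "missing coefficient")
})

test_that("pocket residues are exactly the residues in range", {
  g <- generate_complex(n_residues = 10,
                        pocket_spec = list(pocket_residues = c(3L, 7L, 9L),
                                           pocket_distance = 4.0),
                        seed = 5)
  pr <- pocket_residues(g$complex, pocket_cutoff = 5.0)
  expect_equal(pr$resno, c(3L, 7L, 9L))
  # far ligand -> empty pocket
  iso <- generate_complex(n_residues = 5, seed = 2)
  expect_equal(nrow(pocket_residues(iso$complex)), 0L)
})

test_that("pocket comparison classifies planted edits exactly", {
  g <- generate_complex(n_residues = 12,
                        pocket_spec = list(pocket_residues = 5:8,
                                           pocket_distance = 4.0),
                        seed = 8)
  ref <- complex_sequence(g$complex)
  expect_equal(ref, g$truth$sequence)

  # identical sequence: every pocket residue identical, no insertions
  same <- compare_pockets(g$complex, ref)
  expect_equal(same$n_identical, 4L)
  expect_equal(same$n_substituted + same$n_deleted + same$n_insertions, 0L)

  # single substitution at a pocket position
  chars <- strsplit(ref, "")[[1]]
  chars[6] <- setdiff(c("A", "V"), chars[6])[1]
  one <- compare_pockets(g$complex, paste(chars, collapse = ""))
  expect_equal(one$n_substituted, 1L)
  expect_equal(one$n_identical, 3L)

  # planted edit script: substitutions at pocket positions 7 and 8 plus a
  # one-residue insertion between pocket residues 5 and 6. The insertion
  # sits between two residues that stay identical, which pins the gap
  # (sliding it would break an exact match); the inserted character avoids
  # the neighbourhood so it cannot re-create a match.
  orig <- strsplit(ref, "")[[1]]
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  chars <- orig
  chars[7] <- setdiff(aa, orig[7])[1]
  chars[8] <- setdiff(aa, c(orig[8], chars[7]))[1]
  ins <- setdiff(aa, orig[4:7])[1]
  cmp <- paste(c(chars[1:5], ins, chars[6:12]), collapse = "")
  res <- compare_pockets(g$complex, cmp)
  expect_equal(res$n_substituted, 2L)
  expect_equal(res$n_insertions, 1L)
  expect_equal(res$n_deleted, 0L)
  expect_equal(res$n_identical, 2L)

  # unalignable comparison sequence is refused
  expect_error(compare_pockets(g$complex, strrep("W", 30)), "unreliable")
})
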