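# Independent oracles and small fixture builders shared across tests.
# The alignment oracles enumerate every gapped alignment explicitly and
# never share code with the package's dynamic-programming engine.

# best global alignment score by exhaustive recursion over move strings
# (match / up / left), affine gap runs costing open + extend*(len-1)
enum_global_score <- function(q, s, scheme) {
  qc <- strsplit(q, "")[[1L]]
  sc <- strsplit(s, "")[[1L]]
  M <- scheme$substitution_matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  rec <- function(i, j, last) {
    if (i > length(qc) && j > length(sc)) return(0)
    best <- -Inf
    if (i <= length(qc) && j <= length(sc))
      best <- max(best, M[qc[i], sc[j]] + rec(i + 1L, j + 1L, "m"))
    if (i <= length(qc))
      best <- max(best, -(if (last == "u") ge else go) + rec(i + 1L, j, "u"))
    if (j <= length(sc))
      best <- max(best, -(if (last == "l") ge else go) + rec(i, j + 1L, "l"))
    best
  }
  rec(1L, 1L, "m")
}

all_substrings <- function(x) {
  n <- nchar(x)
  unique(unlist(lapply(seq_len(n), function(i) substring(x, i, i:n))))
}

# best local score = best global score over all substring pairs, floored
# at zero (terminal gap columns only lower a substring alignment's score,
# so the substring maximum covers gap-free-end alignments)
enum_local_score <- function(q, s, scheme) {
  best <- 0
  for (a in all_substrings(q))
    for (b in all_substrings(s))
      best <- max(best, enum_global_score(a, b, scheme))
  best
}

# literal double-loop contact classifier
brute_contact_counts <- function(complex, cutoff) {
  at <- complex$atoms[toupper(complex$atoms$element) != "H", , drop = FALSE]
  prot <- at[at$entity == "protein", , drop = FALSE]
  lig <- at[at$entity == "ligand", , drop = FALSE]
  cls <- function(e) if (toupper(e) %in% c("C", "N", "O")) toupper(e) else "X"
  counts <- setNames(integer(10L), c("CC", "CN", "CO", "CX", "NN", "NO",
                                     "NX", "OO", "OX", "XX"))
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                  (prot$z[i] - lig$z[j])^2)
      if (d <= cutoff) {
        pair <- sort(c(cls(prot$element[i]), cls(lig$element[j])))
        key <- paste0(pair[1L], pair[2L])
        counts[key] <- counts[key] + 1L
      }
    }
  }
  counts
}

random_rigid_transform <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  list(R = R, t = rnorm(3L, sd = 20))
}

apply_rigid <- function(complex, tr) {
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")]) %*% t(tr$R)
  complex$atoms$x <- xyz[, 1L] + tr$t[1L]
  complex$atoms$y <- xyz[, 2L] + tr$t[2L]
  complex$atoms$z <- xyz[, 3L] + tr$t[3L]
  complex
}

# random toy complex: n_prot protein + n_lig ligand heavy atoms in a box
random_complex <- function(seed, n_prot = 20L, n_lig = 10L, box = 12) {
  set.seed(seed)
  n <- n_prot + n_lig
  complex_structure(
    data.frame(entity = rep(c("protein", "ligand"), c(n_prot, n_lig)),
               element = sample(c("C", "N", "O", "S", "P"), n,
                                replace = TRUE),
               atom_name = "ZZ", resname = rep(c("ALA", "LIG"),
                                               c(n_prot, n_lig)),
               resno = c(seq_len(n_prot), rep(900L, n_lig)),
               chain = rep(c("A", "L"), c(n_prot, n_lig)),
               x = runif(n, 0, box), y = runif(n, 0, box),
               z = runif(n, 0, box), stringsAsFactors = FALSE),
    "LIG")
}

# minimal metaproteome entry table built in code
toy_metaproteome <- function(ids, seqs, biome = "gut",
                             species = "Escherichia coli",
                             phylum = "Proteobacteria",
                             fun = "background function") {
  n <- length(ids)
  data.frame(protein_id = ids, sequence = seqs,
             mag_id = paste0("mag_", ids), biome = rep_len(biome, n),
             lineage = NA_character_, species = rep_len(species, n),
             phylum = rep_len(phylum, n),
             function_annotation = rep_len(fun, n),
             stringsAsFactors = FALSE)
}

toy_targets <- function(ids, seqs, class = "human", fun = "target function") {
  n <- length(ids)
  data.frame(target_id = ids, sequence = seqs,
             target_organism = rep_len("Homo sapiens", n),
             target_class = rep_len(class, n),
             function_label = rep_len(fun, n), drug_ids = "",
             stringsAsFactors = FALSE)
}

# hits table built directly for downstream-stage tests
toy_hits <- function(target_id, protein_id, biome = "gut",
                     percent_identity = 60, species = "Escherichia coli",
                     phylum = "Proteobacteria", target_class = "human",
                     function_label = "target function",
                     function_annotation = "target function",
                     is_identical = FALSE) {
  n <- max(lengths(list(target_id, protein_id, biome, percent_identity,
                        species)))
  data.frame(target_id = rep_len(target_id, n),
             target_class = rep_len(target_class, n),
             function_label = rep_len(function_label, n),
             protein_id = rep_len(protein_id, n),
             biome = rep_len(biome, n),
             mag_id = paste0("mag_", rep_len(protein_id, n)),
             percent_identity = rep_len(percent_identity, n),
             e_value = 1e-30,
             species = rep_len(species, n),
             phylum = rep_len(phylum, n),
             function_annotation = rep_len(function_annotation, n),
             is_identical = rep_len(is_identical, n),
             stringsAsFactors = FALSE)
}
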