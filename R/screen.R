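#' Screen drug targets against a metaproteome
#'
#' The core off-target screen: every target is compared against every
#' metaproteome entry in two stages. A local (Smith-Waterman) alignment
#' provides the Karlin-Altschul E-value used for candidate discovery; the
#' reported percent identity is then recomputed on candidates with a
#' global alignment (`identity_mode = "global"`, the default) or taken
#' from the local alignment (`"local"`, the BLAST `pident` convention).
#' A hit is emitted iff the E-value is at or below `evalue_cutoff` AND the
#' identity is strictly above `similarity_threshold`. All qualifying
#' pairs are kept (no best-hit collapsing); output order is deterministic
#' (target_id, then protein_id).
#'
#' @param targets data.frame of target records ([read_targets()]).
#' @param metaproteome data.frame of metaproteome entries
#'   ([read_annotation_table()]).
#' @param scheme a [scoring_scheme()].
#' @param similarity_threshold percent identity call threshold in (0, 100],
#'   strict (default 30: hits must exceed it).
#' @param evalue_cutoff E-value cutoff for candidate discovery.
#' @param identity_mode `"global"` or `"local"` identity convention.
#' @return A data.frame of class `"offtarget_hits"` with columns
#'   `target_id`, `target_class`, `function_label`, `protein_id`, `biome`,
#'   `mag_id`, `percent_identity`, `e_value`, `species`, `phylum`,
#'   `function_annotation`, `is_identical`. `is_identical` requires 100%
#'   identity over the full length of both sequences.
#' @export
screen_targets <- function(targets, metaproteome, scheme = scoring_scheme(),
                           similarity_threshold = 30, evalue_cutoff = 1e-6,
                           identity_mode = c("global", "local")) {
  identity_mode <- match.arg(identity_mode)
  if (!nrow(targets)) stop("no targets")
  if (!nrow(metaproteome)) stop("no metaproteome entries")
  if (!(similarity_threshold > 0 && similarity_threshold <= 100))
    stop("similarity_threshold must be in (0, 100]")
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive")

  ss <- lapply(metaproteome$sequence, encode_sequence, scheme = scheme)
  mlen <- nchar(metaproteome$sequence)
  rows <- vector("list", nrow(targets))
  for (t in seq_len(nrow(targets))) {
    qenc <- encode_sequence(targets$sequence[t], scheme, targets$target_id[t])
    loc <- score_pairs_cpp(rep(list(qenc), length(ss)), ss,
                           scheme$substitution_matrix, scheme$gap_open,
                           scheme$gap_extend, TRUE)
    ev <- evalue(loc, length(qenc), mlen, scheme)
    cand <- which(ev <= evalue_cutoff)
    if (!length(cand)) next
    pid <- numeric(length(cand))
    for (k in seq_along(cand)) {
      j <- cand[k]
      aln <- if (identity_mode == "global")
        global_align(targets$sequence[t], metaproteome$sequence[j], scheme)
      else local_align(targets$sequence[t], metaproteome$sequence[j], scheme)
      pid[k] <- aln$percent_identity
    }
    keep <- pid > similarity_threshold
    if (!any(keep)) next
    j <- cand[keep]
    rows[[t]] <- data.frame(
      target_id = targets$target_id[t],
      target_class = targets$target_class[t],
      function_label = targets$function_label[t],
      protein_id = metaproteome$protein_id[j],
      biome = metaproteome$biome[j],
      mag_id = metaproteome$mag_id[j],
      percent_identity = pid[keep],
      e_value = ev[j],
      species = metaproteome$species[j],
      phylum = metaproteome$phylum[j],
      function_annotation = metaproteome$function_annotation[j],
      is_identical = targets$sequence[t] == metaproteome$sequence[j],
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  if (is.null(hits))
    hits <- data.frame(target_id = character(0), target_class = character(0),
                       function_label = character(0),
                       protein_id = character(0), biome = character(0),
                       mag_id = character(0), percent_identity = numeric(0),
                       e_value = numeric(0), species = character(0),
                       phylum = character(0),
                       function_annotation = character(0),
                       is_identical = logical(0), stringsAsFactors = FALSE)
  hits <- hits[order(hits$target_id, hits$protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "similarity_threshold") <- similarity_threshold
  attr(hits, "evalue_cutoff") <- evalue_cutoff
  attr(hits, "identity_mode") <- identity_mode
  class(hits) <- c("offtarget_hits", "data.frame")
  hits
}

#' Identical-match counts per biome and target class
#'
#' Counts *unique* metaproteome proteins that are identical (full-length,
#' 100% identity) to at least one target, grouped by biome and target
#' class. A protein identical to several targets is counted once.
#'
#' @param hits an `"offtarget_hits"` data.frame from [screen_targets()].
#' @return A data.frame `biome` x `target_class` with an
#'   `n_identical_proteins` count (all six cells present, zero-filled).
#' @export
identical_matches <- function(hits) {
  grid <- expand.grid(biome = BIOMES, target_class = c("human", "pathogen"),
                      stringsAsFactors = FALSE)
  grid$n_identical_proteins <- 0L
  id <- hits[hits$is_identical, , drop = FALSE]
  if (nrow(id)) {
    id <- id[!duplicated(id[c("biome", "target_class", "protein_id")]), ,
             drop = FALSE]
    tab <- aggregate(list(n = id$protein_id),
                     id[c("biome", "target_class")], length)
    m <- match(paste(grid$biome, grid$target_class),
               paste(tab$biome, tab$target_class))
    grid$n_identical_proteins[!is.na(m)] <- tab$n[m[!is.na(m)]]
  }
  grid
}

#' Function concordance between targets and their hits
#'
#' Restricts hits to those strictly above `function_threshold` percent
#' identity (the stricter cutoff at which shared function is a reasonable
#' inference) and tabulates (target function label, metaproteome function
#' annotation) pairs. Pairs whose strings match exactly are flagged
#' `"identical function"`, all others `"other"` -- including the
#' biologically interesting mappings onto `"hypothetical protein"`.
#'
#' @param hits an `"offtarget_hits"` data.frame.
#' @param function_threshold strict percent-identity cutoff (default 50).
#' @return A data.frame with `function_label`, `function_annotation`,
#'   `concordance`, `n`.
#' @export
function_concordance <- function(hits, function_threshold = 50) {
  keep <- hits$percent_identity > function_threshold
  sub <- hits[keep, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(function_label = character(0),
                      function_annotation = character(0),
                      concordance = character(0), n = integer(0),
                      stringsAsFactors = FALSE))
  tab <- aggregate(list(n = sub$target_id),
                   sub[c("function_label", "function_annotation")], length)
  tab$concordance <- ifelse(tab$function_label == tab$function_annotation,
                            "identical function", "other")
  tab <- tab[order(-tab$n, tab$function_label), ,
             drop = FALSE][c("function_label", "function_annotation",
                             "concordance", "n")]
  rownames(tab) <- NULL
  tab
}

#' Summarise an off-target screen
#'
#' @param hits an `"offtarget_hits"` data.frame.
#' @return A list with `by_group` (per target_class x biome: `n_hits`,
#'   `mean_identity`, `n_identical`) and `by_target` (per target:
#'   `n_hits`, `n_species`).
#' @export
screen_summary <- function(hits) {
  if (!nrow(hits)) {
    return(list(by_group = data.frame(target_class = character(0),
                                      biome = character(0),
                                      n_hits = integer(0),
                                      mean_identity = numeric(0),
                                      n_identical = integer(0)),
                by_target = data.frame(target_id = character(0),
                                       n_hits = integer(0),
                                       n_species = integer(0))))
  }
  by_group <- aggregate(list(n_hits = hits$protein_id),
                        hits[c("target_class", "biome")], length)
  mi <- aggregate(list(mean_identity = hits$percent_identity),
                  hits[c("target_class", "biome")], mean)
  ni <- aggregate(list(n_identical = hits$is_identical),
                  hits[c("target_class", "biome")], sum)
  by_group <- merge(merge(by_group, mi), ni)
  by_target <- do.call(rbind, lapply(split(hits, hits$target_id), function(h)
    data.frame(target_id = h$target_id[1L], n_hits = nrow(h),
               n_species = length(unique(h$species[!is.na(h$species)])),
               stringsAsFactors = FALSE)))
  rownames(by_target) <- NULL
  list(by_group = by_group[order(by_group$target_class, by_group$biome), ],
       by_target = by_target)
}

#' @export
print.offtarget_hits <- function(x, ...) {
  cat("Off-target hits:", nrow(x), "hits,",
      length(unique(x$target_id)), "targets; identity >",
      attr(x, "similarity_threshold"), "%, E <=",
      attr(x, "evalue_cutoff"), "(", attr(x, "identity_mode"),
      "identity )\n")
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Export hits as BLAST outfmt-6-like TSV
#'
#' Columns: qseqid sseqid pident length evalue score qcovs -- the `length`,
#' `score` and `qcovs` columns are filled by re-aligning each hit pair.
#'
#' @param hits an `"offtarget_hits"` data.frame.
#' @param targets,metaproteome the inputs used for the screen.
#' @param path output TSV path.
#' @param scheme a [scoring_scheme()].
#' @return `path`, invisibly.
#' @export
export_hits_tsv <- function(hits, targets, metaproteome, path,
                            scheme = scoring_scheme()) {
  mode <- attr(hits, "identity_mode")
  out <- data.frame(qseqid = hits$target_id, sseqid = hits$protein_id,
                    pident = hits$percent_identity, length = NA_integer_,
                    evalue = hits$e_value, score = NA_real_,
                    qcovs = NA_real_)
  for (k in seq_len(nrow(hits))) {
    q <- targets$sequence[match(hits$target_id[k], targets$target_id)]
    s <- metaproteome$sequence[match(hits$protein_id[k],
                                     metaproteome$protein_id)]
    aln <- if (identical(mode, "local")) local_align(q, s, scheme)
           else global_align(q, s, scheme)
    out$length[k] <- aln$n_columns
    out$score[k] <- aln$score
    out$qcovs[k] <- round(100 * aln$query_coverage, 1)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
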