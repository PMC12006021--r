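#' Assign targets and drugs to microbiome-affecting groups
#'
#' A target is *affecting* iff it has at least one off-target hit; every
#' target lands in exactly one group. At the drug level a drug is
#' affecting if ANY of its linked targets is affecting (the least-selective
#' reading; recorded in the result so downstream outputs can state it).
#' Targets without a drug link trigger a warning and are excluded from the
#' drug-level analysis only.
#'
#' @param targets data.frame of target records.
#' @param hits an `"offtarget_hits"` data.frame from [screen_targets()].
#' @param links optional data.frame `drug_id`, `target_id`
#'   ([read_drug_target_links()]); required for drug-level grouping.
#' @return An object of class `"group_assignment"`: list with `targets`
#'   (`target_id`, `group`) and, when links are given, `drugs`
#'   (`drug_id`, `group`).
#' @export
assign_groups <- function(targets, hits, links = NULL) {
  affecting <- unique(hits$target_id)
  tg <- data.frame(target_id = targets$target_id,
                   group = ifelse(targets$target_id %in% affecting,
                                  "affecting", "non_affecting"),
                   stringsAsFactors = FALSE)
  drugs <- NULL
  if (!is.null(links)) {
    unlinked <- setdiff(tg$target_id, links$target_id)
    if (length(unlinked))
      warning(length(unlinked), " target(s) without drug link excluded ",
              "from drug-level analysis: ",
              paste(head(unlinked, 5L), collapse = ", "))
    lk <- merge(links, tg, by = "target_id")
    drugs <- aggregate(list(affecting = lk$group == "affecting"),
                       list(drug_id = lk$drug_id), any)
    drugs <- data.frame(drug_id = drugs$drug_id,
                        group = ifelse(drugs$affecting, "affecting",
                                       "non_affecting"),
                        stringsAsFactors = FALSE)
    drugs <- drugs[order(drugs$drug_id), , drop = FALSE]
    rownames(drugs) <- NULL
  }
  structure(list(targets = tg, drugs = drugs, rule = "any-affecting-target"),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Group assignment (drug rule:", x$rule, ")\n")
  print(table(x$targets$group))
  if (!is.null(x$drugs)) print(table(x$drugs$group))
  invisible(x)
}

# side-effect rows restricted to drugs with a group; errors on empty input
filter_side_effects <- function(assignment, side_effects) {
  stopifnot(inherits(assignment, "group_assignment"))
  if (is.null(assignment$drugs))
    stop("assignment lacks drug-level groups: pass links to assign_groups()")
  if (!nrow(side_effects)) stop("empty side-effect table")
  se <- side_effects[side_effects$drug_id %in% assignment$drugs$drug_id, ,
                     drop = FALSE]
  se$group <- assignment$drugs$group[match(se$drug_id,
                                           assignment$drugs$drug_id)]
  se
}

#' Partition symptoms into unique and shared sets
#'
#' Side-effect rows are first filtered to drugs present in the group
#' assignment. A symptom is unique to a group if it is reported for at
#' least one of that group's drugs and none of the other group's; it is
#' shared when both groups report it. Symptoms observed for no linked drug
#' are dropped.
#'
#' @param assignment a [assign_groups()] result with drug-level groups.
#' @param side_effects a [read_side_effect_table()] data.frame.
#' @return A list with character vectors `unique_affecting`,
#'   `unique_non_affecting`, `shared`, and a per-symptom data.frame
#'   `table` (`symptom`, `soc`, `n_affecting`, `n_non_affecting`,
#'   `membership`).
#' @export
symptom_partition <- function(assignment, side_effects) {
  se <- filter_side_effects(assignment, side_effects)
  if (!nrow(se)) stop("no side-effect rows for drugs in the assignment")
  symptoms <- sort(unique(se$symptom))
  n_a <- vapply(symptoms, function(s)
    length(unique(se$drug_id[se$symptom == s & se$group == "affecting"])), 0L)
  n_n <- vapply(symptoms, function(s)
    length(unique(se$drug_id[se$symptom == s & se$group == "non_affecting"])),
    0L)
  membership <- ifelse(n_a > 0L & n_n > 0L, "shared",
                       ifelse(n_a > 0L, "unique_affecting",
                              "unique_non_affecting"))
  soc <- se$soc[match(symptoms, se$symptom)]
  tab <- data.frame(symptom = symptoms, soc = soc, n_affecting = n_a,
                    n_non_affecting = n_n, membership = membership,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(unique_affecting = symptoms[membership == "unique_affecting"],
       unique_non_affecting = symptoms[membership == "unique_non_affecting"],
       shared = symptoms[membership == "shared"],
       table = tab)
}

#' Percent change in normalized symptom prevalence between groups
#'
#' For each *shared* symptom the normalized prevalence in group g is the
#' fraction of that group's drugs reporting the symptom,
#' \eqn{p_g = n_g / N_g}, and the screen statistic is the relative change
#' \eqn{100 (p_a - p_n) / p_n}. Only symptoms whose absolute change
#' strictly exceeds `min_change` are returned, sorted by absolute change
#' (the computation uses integer counts so that an exact boundary value is
#' filtered reliably). An optional permutation null (shuffling drug group
#' labels) attaches a two-sided p-value per symptom.
#'
#' @param assignment a [assign_groups()] result with drug-level groups.
#' @param side_effects a [read_side_effect_table()] data.frame.
#' @param min_change strict percent-change filter (default 10).
#' @param n_perm number of label permutations for the optional null
#'   (0 = off).
#' @param seed RNG seed for the permutation null.
#' @return A data.frame of class `"symptom_prevalence"`: `symptom`, `soc`,
#'   `n_affecting`, `n_non_affecting`, `p_affecting`, `p_non_affecting`,
#'   `percent_change` (and `perm_p` when `n_perm > 0`). The unfiltered
#'   shared-symptom table is attached as attribute `"shared_all"`; group
#'   sizes as `"group_sizes"`.
#' @export
prevalence_change <- function(assignment, side_effects, min_change = 10,
                              n_perm = 0, seed = NULL) {
  se <- filter_side_effects(assignment, side_effects)
  sizes <- table(factor(assignment$drugs$group,
                        c("affecting", "non_affecting")))
  if (any(sizes == 0L)) stop("a group has zero drugs")
  N_a <- as.integer(sizes[["affecting"]])
  N_n <- as.integer(sizes[["non_affecting"]])
  part <- symptom_partition(assignment, side_effects)
  tab <- part$table[part$table$membership == "shared", , drop = FALSE]
  if (!nrow(tab))
    stop("no shared symptoms between the two groups")
  # integer-count form keeps exact boundary cases exact
  num <- tab$n_affecting * N_n - tab$n_non_affecting * N_a
  tab$p_affecting <- tab$n_affecting / N_a
  tab$p_non_affecting <- tab$n_non_affecting / N_n
  tab$percent_change <- (100 * num) / (tab$n_non_affecting * N_a)
  if (n_perm > 0) {
    tab$perm_p <- permutation_pvalues(assignment, se, tab, n_perm, seed)
  }
  out <- tab[abs(tab$percent_change) > min_change, , drop = FALSE]
  out <- out[order(-abs(out$percent_change), out$symptom), , drop = FALSE]
  out$membership <- NULL
  rownames(out) <- NULL
  attr(out, "shared_all") <- tab
  attr(out, "group_sizes") <- c(affecting = N_a, non_affecting = N_n)
  class(out) <- c("symptom_prevalence", "data.frame")
  out
}

permutation_pvalues <- function(assignment, se, tab, n_perm, seed) {
  drugs <- assignment$drugs
  obs <- abs(tab$percent_change)
  N_a <- sum(drugs$group == "affecting")
  has <- lapply(tab$symptom, function(s) unique(se$drug_id[se$symptom == s]))
  exceed <- integer(nrow(tab))
  with_seed(if (is.null(seed)) 1L else seed, {
    for (r in seq_len(n_perm)) {
      perm <- sample(drugs$drug_id)
      aff <- perm[seq_len(N_a)]
      for (k in seq_len(nrow(tab))) {
        na <- sum(has[[k]] %in% aff)
        nn <- length(has[[k]]) - na
        pc <- if (nn == 0L) Inf
          else abs((100 * (na * (nrow(drugs) - N_a) - nn * N_a)) /
                     (nn * N_a))
        if (pc >= obs[k]) exceed[k] <- exceed[k] + 1L
      }
    }
  })
  (exceed + 1L) / (n_perm + 1L)
}

#' Roll up enriched symptoms by system organ class
#'
#' Counts, per system organ class, how many filtered symptoms are more
#' prevalent in the affecting group (`n_up`, percent change > 0) and in
#' the non-affecting group (`n_down`), with the number of shared symptoms
#' of that class as denominator.
#'
#' @param prevalences a [prevalence_change()] result.
#' @return A data.frame `soc`, `n_up`, `n_down`, `n_shared`.
#' @export
soc_rollup <- function(prevalences) {
  shared_all <- attr(prevalences, "shared_all")
  if (!nrow(prevalences))
    return(data.frame(soc = character(0), n_up = integer(0),
                      n_down = integer(0), n_shared = integer(0),
                      stringsAsFactors = FALSE))
  socs <- sort(unique(prevalences$soc))
  out <- data.frame(
    soc = socs,
    n_up = vapply(socs, function(s)
      sum(prevalences$soc == s & prevalences$percent_change > 0), 0L),
    n_down = vapply(socs, function(s)
      sum(prevalences$soc == s & prevalences$percent_change < 0), 0L),
    n_shared = vapply(socs, function(s)
      if (is.null(shared_all)) NA_integer_ else sum(shared_all$soc == s),
      0L),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-(out$n_up + out$n_down), out$soc), , drop = FALSE]
}
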