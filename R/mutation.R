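# Tumor mutation burden, 2x2 mutation-frequency contrasts between score
# groups, score-TMB correlation, oncoprint-style summaries and bivariate
# (TMB x score group) survival stratification.

#' Variant classifications counted as non-synonymous
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

#' Tumor mutation burden per sample
#'
#' Counts each sample's non-synonymous records. Samples listed in
#' `sample_ids` but absent from the mutation table count 0 (wild-type
#' everywhere). TMB groups split at the threshold: counts strictly above it
#' are "high".
#'
#' @param mut Mutation table (`sample_id`, `gene`, `variant_classification`).
#' @param sample_ids Cohort sample ids (defaults to those present in `mut`).
#' @param threshold Numeric split, or `"median"` (default).
#' @return `data.frame` with `sample_id`, `nonsyn_count`, `tmb_group`,
#'   `threshold_used`.
#' @export
compute_tmb <- function(mut, sample_ids = NULL, threshold = "median") {
  ns <- mut[mut$variant_classification %in% nonsynonymous_classes(), ]
  counts <- table(ns$sample_id)
  if (is.null(sample_ids)) sample_ids <- sort(unique(mut$sample_id))
  absent <- setdiff(sample_ids, mut$sample_id)
  if (length(absent))
    message(length(absent), " sample(s) absent from the mutation table; counted as 0")
  n <- stats::setNames(rep(0L, length(sample_ids)), sample_ids)
  hit <- intersect(names(counts), sample_ids)
  n[hit] <- as.integer(counts[hit])
  thr <- if (identical(threshold, "median")) stats::median(n) else threshold
  data.frame(sample_id = sample_ids, nonsyn_count = as.integer(n),
             tmb_group = ifelse(n > thr, "high", "low"),
             threshold_used = thr, row.names = NULL, stringsAsFactors = FALSE)
}

#' Yates-corrected chi-square on a 2x2 wild/mutant table
#'
#' Low-level contingency test used for the per-gene score-group contrasts.
#' Continuity (Yates) correction is applied, df = 1. A zero margin makes the
#' test undefined: p is `NA` with `degenerate = TRUE`.
#'
#' @param high_wild,high_mut,low_wild,low_mut Cell counts.
#' @return List with `chi2`, `p`, `degenerate`.
#' @export
contingency_chisq <- function(high_wild, high_mut, low_wild, low_mut) {
  tab <- matrix(c(high_wild, high_mut, low_wild, low_mut), nrow = 2,
                byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(chi2 = NA_real_, p = NA_real_, degenerate = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value),
       degenerate = FALSE)
}

#' Mutation-frequency contrast between score groups for one gene
#'
#' A sample is "mutant" for the gene if it has at least one non-synonymous
#' record; samples absent from the mutation table are wild-type. Builds the
#' 2x2 high/low x wild/mutant table and applies [contingency_chisq].
#'
#' @param mut Mutation table.
#' @param groups Named vector of "high"/"low" per sample (both present).
#' @param gene Gene symbol.
#' @return `data.frame` row: `gene`, `high_wild`, `high_mut`, `low_wild`,
#'   `low_mut`, `chi2`, `p`, `degenerate`.
#' @export
gene_group_chisq <- function(mut, groups, gene) {
  groups <- groups[!is.na(groups)]
  if (length(unique(groups)) < 2) stop("both score groups must be non-empty")
  ns <- mut[mut$variant_classification %in% nonsynonymous_classes() &
              mut$gene == gene, ]
  mutant <- names(groups) %in% ns$sample_id
  hw <- sum(groups == "high" & !mutant); hm <- sum(groups == "high" & mutant)
  lw <- sum(groups == "low" & !mutant);  lm <- sum(groups == "low" & mutant)
  ct <- contingency_chisq(hw, hm, lw, lm)
  data.frame(gene = gene, high_wild = hw, high_mut = hm, low_wild = lw,
             low_mut = lm, chi2 = ct$chi2, p = ct$p,
             degenerate = ct$degenerate, stringsAsFactors = FALSE)
}

#' Ranked mutation-frequency table and oncoprint matrix
#'
#' Ranks genes by the overall fraction of mutated samples (ties broken
#' alphabetically), reports per-group frequencies, and builds a sample x
#' gene classification matrix in which samples carrying two or more
#' non-synonymous records of a gene are collapsed to `"Multi_Hit"`.
#'
#' @param mut Mutation table.
#' @param groups Named vector of "high"/"low" per sample.
#' @param top_n Number of top-ranked genes to keep.
#' @return List: `frequencies` (`data.frame` with overall and per-group
#'   mutated fractions) and `oncoprint` (character matrix, samples x genes,
#'   `""` = wild-type).
#' @export
mutation_frequency_table <- function(mut, groups, top_n = 20) {
  samples <- names(groups)
  ns <- mut[mut$variant_classification %in% nonsynonymous_classes() &
              mut$sample_id %in% samples, ]
  if (nrow(ns) == 0)
    return(list(frequencies = data.frame(), oncoprint = matrix("", 0, 0)))
  per_gene <- tapply(ns$sample_id, ns$gene, function(s) length(unique(s)))
  freq <- as.numeric(per_gene) / length(samples)
  ord <- order(-freq, names(per_gene))
  genes <- names(per_gene)[ord][seq_len(min(top_n, length(per_gene)))]

  n_high <- sum(groups == "high"); n_low <- sum(groups == "low")
  rows <- lapply(genes, function(g) {
    mut_samples <- unique(ns$sample_id[ns$gene == g])
    hm <- sum(groups[mut_samples] == "high")
    lm <- sum(groups[mut_samples] == "low")
    data.frame(gene = g, n_mutated = length(mut_samples),
               freq = round(length(mut_samples) / length(samples), 4),
               high_mut = hm, high_freq = round(hm / n_high, 4),
               low_mut = lm, low_freq = round(lm / n_low, 4),
               stringsAsFactors = FALSE)
  })
  frequencies <- do.call(rbind, rows)
  frequencies$rank <- seq_len(nrow(frequencies))

  onco <- matrix("", length(samples), length(genes),
                 dimnames = list(samples, genes))
  key <- ns[ns$gene %in% genes, ]
  if (nrow(key)) {
    agg <- stats::aggregate(
      variant_classification ~ sample_id + gene, data = key,
      FUN = function(v) if (length(v) >= 2) "Multi_Hit" else v[1L])
    for (i in seq_len(nrow(agg)))
      onco[agg$sample_id[i], agg$gene[i]] <- agg$variant_classification[i]
  }
  list(frequencies = frequencies, oncoprint = onco)
}

#' Spearman correlation between score and TMB
#'
#' @param scores Named numeric score per sample.
#' @param tmb Named numeric non-synonymous count per sample.
#' @return List with `rho` and `p` (two-sided, tie-corrected).
#' @export
score_tmb_correlation <- function(scores, tmb) {
  shared <- intersect(names(scores), names(tmb))
  if (length(shared) < 3) stop("need >= 3 paired samples")
  x <- scores[shared]; y <- tmb[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Survival stratified jointly by TMB and score group
#'
#' Builds the four TMB x score combination groups, drops empty ones with a
#' warning, and reports per-group KM curves plus a global log-rank test.
#'
#' @param tmb_groups,ici_groups Named "high"/"low" vectors per sample.
#' @param clinical Clinical table with `sample_id`, `os_time`, `os_event`.
#' @return List: `groups` (per-sample combination label), `km` (named list
#'   of [kaplan_meier] curves), `logrank` (chi2/df/p).
#' @export
bivariate_survival <- function(tmb_groups, ici_groups, clinical) {
  ids <- intersect(names(tmb_groups), intersect(names(ici_groups),
                                                clinical$sample_id))
  combo <- paste0("TMB_", tmb_groups[ids], "/ICI_", ici_groups[ids])
  names(combo) <- ids
  all_levels <- as.vector(outer(c("high", "low"), c("high", "low"),
                                function(a, b) paste0("TMB_", a, "/ICI_", b)))
  empty <- setdiff(all_levels, unique(combo))
  if (length(empty))
    warning("empty combination group(s) dropped: ",
            paste(empty, collapse = ", "))
  cl <- clinical[match(ids, clinical$sample_id), ]
  km <- lapply(split(seq_along(ids), combo), function(idx)
    kaplan_meier(cl$os_time[idx], cl$os_event[idx]))
  lr <- logrank_test(cl$os_time, cl$os_event, combo)
  list(groups = combo, km = km, logrank = lr)
}
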