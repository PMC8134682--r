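# End-to-end orchestration: simulate (or load) a cohort, deconvolve,
# cluster, find DEGs, build the ICI score, and run the downstream survival,
# mutation, enrichment and response analyses. Every stage writes plain TSV
# artifacts plus a JSON manifest with content hashes, so a rerun with the
# same config and seed is byte-identical.

#' Default pipeline configuration
#'
#' Returns the full configuration list with documented defaults; any entry
#' can be overridden through `...`. Defaults are desk-scale: a 300-sample
#' synthetic cohort, 200 consensus repetitions, 30 shadow-selection
#' iterations, 200 GSEA permutations.
#'
#' @param ... Named overrides.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,               # master seed; stage streams derive from it
    n_samples = 300L,        # synthetic cohort size
    n_background_genes = 300L,
    noise_sd = 0.2,          # multiplicative expression noise
    log_hr = -1,             # hazard log-HR per SD of latent immune level
    censor_rate = 0.3,
    k = 3L,                  # pinned cluster count (ICI and gene clusters)
    consensus_reps = 200L,
    consensus_subsample = 0.8,
    nu_grid = c(0.25, 0.5, 0.75),
    fc_threshold = 1.0,      # |log2 FC| threshold for DEGs
    fc_scale = "log2",
    alpha = 0.05,
    boruta = TRUE,
    boruta_iter = 30L,
    boruta_trees = 100L,
    min_group_fraction = 0.1,
    gsea_perm = 200L,
    gsea_weight = 1,
    mutation_top_n = 20L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config entr(ies): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = c("pipeline_config", "list"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full ICI analysis pipeline
#'
#' Stages, in dependency order: cohort simulation; cell-fraction
#' deconvolution; immune scoring; consensus clustering of fractions into
#' immune subtypes (labels canonicalized A/B/C by decreasing mean immune
#' score); one-vs-rest DEG selection; consensus clustering of samples on DEG
#' expression (gene clusters); signature A/B partition and optional
#' shadow-feature reduction; ICI score with maximally selected survival
#' cutoff; survival, mutation, enrichment and response statistics. All stage
#' tables land in `out_dir` together with the serialized config and a
#' manifest (file MD5 hashes per stage).
#'
#' @param config A [pipeline_config] list.
#' @param out_dir Output directory (created if missing).
#' @param cohort Optional pre-built [simulate_cohort] object; by default one
#'   is generated from the config.
#' @return Invisibly, a list with every stage's in-memory result plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, cohort = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("iciscope")),
                   seed = config$seed, stages = list())
  files_of <- function(stage, paths) {
    manifest$stages[[stage]] <<- lapply(stats::setNames(paths, basename(paths)),
                                        function(p) unname(tools::md5sum(p)))
  }
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  ## 1. cohort -----------------------------------------------------------
  if (is.null(cohort))
    cohort <- simulate_cohort(n_samples = config$n_samples,
                              n_background_genes = config$n_background_genes,
                              noise_sd = config$noise_sd,
                              log_hr = config$log_hr,
                              censor_rate = config$censor_rate,
                              seed = config$seed)
  expr <- cohort$expression
  log_expr <- to_log2(expr)
  p_expr <- file.path(out_dir, "expression.tsv")
  write_expression_matrix(expr, p_expr)
  p_clin <- file.path(out_dir, "clinical.tsv")
  write_clinical(cohort$clinical, p_clin)
  p_maf <- file.path(out_dir, "mutations.maf")
  write_maf(cohort$mutations, p_maf)
  p_truth <- file.path(out_dir, "truth_fractions.tsv")
  write_tsv(data.frame(sample_id = rownames(cohort$true_fractions),
                       cohort$true_fractions, check.names = FALSE),
            p_truth)
  files_of("simulate", c(p_expr, p_clin, p_maf, p_truth))

  ## 2. deconvolution ----------------------------------------------------
  deconv <- svr_deconvolve(expr, cohort$signature, nu_grid = config$nu_grid,
                           seed = config$seed + 10L)
  p_frac <- write_tsv(data.frame(sample_id = rownames(deconv$fractions),
                                 deconv$fractions, check.names = FALSE),
                      file.path(out_dir, "cell_fractions.tsv"))
  files_of("deconvolution", p_frac)

  ## 3. immune score (cytotoxic-marker enrichment) -----------------------
  cytotoxic_markers <- rownames(cohort$signature)[
    sub("\\.M\\d+$", "", rownames(cohort$signature)) %in% CYTOTOXIC_TYPES]
  immune_score <- ssgsea_score(log_expr, cytotoxic_markers)
  p_imm <- write_tsv(data.frame(sample_id = names(immune_score),
                                immune_score = as.numeric(immune_score)),
                     file.path(out_dir, "immune_scores.tsv"))
  files_of("immune_score", p_imm)

  ## 4. immune subtypes (consensus on fractions) -------------------------
  cc_ici <- consensus_cluster(deconv$fractions, k_range = 2:min(6, config$k + 3),
                              reps = config$consensus_reps,
                              subsample = config$consensus_subsample,
                              seed = config$seed + 20L)
  ici_cluster <- canonicalize_clusters(cc_ici$labels[[as.character(config$k)]],
                                       immune_score)
  p_ici_cl <- write_tsv(data.frame(sample_id = names(ici_cluster),
                                   ici_cluster = unname(ici_cluster),
                                   chosen_k_delta_area = cc_ici$chosen_k,
                                   k_used = config$k),
                        file.path(out_dir, "ici_clusters.tsv"))
  files_of("ici_clusters", p_ici_cl)

  ## 5. DEGs -------------------------------------------------------------
  degs <- select_degs(log_expr, ici_cluster, fc_threshold = config$fc_threshold,
                      alpha = config$alpha, fc_scale = config$fc_scale)
  deg_genes <- attr(degs, "deg_genes")
  p_degs <- write_tsv(degs, file.path(out_dir, "degs.tsv"))
  files_of("degs", p_degs)
  if (length(deg_genes) < 4)
    stop("stage degs: fewer than 4 DEGs found; cannot build signatures")

  ## 6. gene clusters (consensus of samples on DEG expression) -----------
  deg_expr <- log_expr[deg_genes, , drop = FALSE]
  deg_z <- t(scale(t(unclass(deg_expr))))
  cc_gene <- consensus_cluster(t(deg_z), k_range = 2:min(6, config$k + 3),
                               reps = config$consensus_reps,
                               subsample = config$consensus_subsample,
                               seed = config$seed + 30L)
  gene_cluster <- canonicalize_clusters(cc_gene$labels[[as.character(config$k)]],
                                        immune_score)
  p_gc <- write_tsv(data.frame(sample_id = names(gene_cluster),
                               gene_cluster = unname(gene_cluster)),
                    file.path(out_dir, "gene_clusters.tsv"))
  files_of("gene_clusters", p_gc)

  ## 7. signatures A/B (+ optional shadow-feature reduction) -------------
  cluster_order <- rev(sort(unique(gene_cluster)))  # ascending immune level
  partition <- assign_signatures(deg_expr, gene_cluster, cluster_order)
  if (isTRUE(config$boruta)) {
    bor <- boruta_select(t(unclass(deg_expr)), gene_cluster,
                         n_iter = config$boruta_iter,
                         num_trees = config$boruta_trees,
                         seed = config$seed + 40L)
    keep_a <- intersect(partition$genes_A, bor$confirmed)
    keep_b <- intersect(partition$genes_B, bor$confirmed)
    if (length(keep_a) >= 2) partition$genes_A <- keep_a else
      warning("shadow selection left < 2 signature-A genes; keeping unreduced set")
    if (length(keep_b) >= 2) partition$genes_B <- keep_b else
      warning("shadow selection left < 2 signature-B genes; keeping unreduced set")
  }
  p_sig <- write_tsv(data.frame(
    gene = c(partition$genes_A, partition$genes_B),
    signature = rep(c("A", "B"),
                    c(length(partition$genes_A), length(partition$genes_B)))),
    file.path(out_dir, "signatures.tsv"))
  files_of("signatures", p_sig)

  ## 8. ICI score + cutoff -----------------------------------------------
  scores <- compute_ici_score(log_expr, partition)
  clin <- cohort$clinical[match(scores$sample_id, cohort$clinical$sample_id), ]
  cut <- best_cutoff(scores$ici_score, clin$os_time, clin$os_event,
                     min_group_fraction = config$min_group_fraction)
  scores <- assign_score_groups(scores, cut$cutoff)
  ici_groups <- stats::setNames(scores$group, scores$sample_id)
  p_score <- write_tsv(scores, file.path(out_dir, "ici_scores.tsv"))
  files_of("ici_score", p_score)

  ## 9. survival ----------------------------------------------------------
  lr <- logrank_test(clin$os_time, clin$os_event, scores$group)
  km <- lapply(split(seq_len(nrow(clin)), scores$group), function(idx)
    kaplan_meier(clin$os_time[idx], clin$os_event[idx]))
  hr <- cox_hr(clin$os_time, clin$os_event, scores$group,
               high_level = "high")
  p_surv <- write_tsv(data.frame(test = "logrank_high_vs_low",
                                 chi2 = lr$chi2, df = lr$df, p = lr$p,
                                 hr = hr$hr, hr_ci_lo = hr$ci_lo,
                                 hr_ci_hi = hr$ci_hi, hr_p = hr$p),
                      file.path(out_dir, "survival.tsv"))
  files_of("survival", p_surv)

  ## 10. mutation ----------------------------------------------------------
  tmb <- compute_tmb(cohort$mutations, scores$sample_id)
  tmb_counts <- stats::setNames(tmb$nonsyn_count, tmb$sample_id)
  corr <- score_tmb_correlation(stats::setNames(scores$ici_score,
                                                scores$sample_id), tmb_counts)
  freq <- mutation_frequency_table(cohort$mutations, ici_groups,
                                   top_n = config$mutation_top_n)
  contrasts <- do.call(rbind, lapply(freq$frequencies$gene, function(g)
    gene_group_chisq(cohort$mutations, ici_groups, g)))
  tmb_groups <- stats::setNames(tmb$tmb_group, tmb$sample_id)
  bisurv <- bivariate_survival(tmb_groups, ici_groups, cohort$clinical)
  p_tmb <- write_tsv(tmb, file.path(out_dir, "tmb.tsv"))
  p_con <- write_tsv(contrasts, file.path(out_dir, "mutation_contrasts.tsv"))
  p_cor <- write_tsv(data.frame(spearman_rho = corr$rho, p = corr$p,
                                bivariate_logrank_chi2 = bisurv$logrank$chi2,
                                bivariate_logrank_p = bisurv$logrank$p),
                     file.path(out_dir, "tmb_correlation.tsv"))
  files_of("mutation", c(p_tmb, p_con, p_cor))

  ## 11. enrichment --------------------------------------------------------
  rank_tab <- moderated_t_test(log_expr, scores$group, "high")
  ranks <- stats::setNames(rank_tab$t, rank_tab$gene)
  marker_sets <- split(rownames(cohort$signature),
                       sub("\\.M\\d+$", "", rownames(cohort$signature)))
  gsea <- preranked_gsea(ranks, marker_sets, n_perm = config$gsea_perm,
                         weight = config$gsea_weight,
                         seed = config$seed + 50L)
  ora <- hypergeometric_ora(deg_genes, marker_sets, rownames(log_expr))
  p_gsea <- write_tsv(as.data.frame(gsea), file.path(out_dir, "gsea.tsv"))
  p_ora <- write_tsv(ora, file.path(out_dir, "ora.tsv"))
  files_of("enrichment", c(p_gsea, p_ora))

  ## 12. response ----------------------------------------------------------
  responder <- as_responder(cohort$response)
  roc <- roc_auc(stats::setNames(scores$ici_score, scores$sample_id)[names(responder)],
                 responder)
  rr <- response_rate_table(cohort$response, ici_groups)
  p_resp <- write_tsv(data.frame(auc = roc$auc, rr_chi2 = rr$chi2,
                                 rr_df = rr$df, rr_p = rr$p),
                      file.path(out_dir, "response.tsv"))
  files_of("response", p_resp)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(cohort = cohort, deconv = deconv,
                 immune_score = immune_score, cc_ici = cc_ici,
                 ici_cluster = ici_cluster, degs = degs,
                 gene_cluster = gene_cluster, partition = partition,
                 scores = scores, cutoff = cut, logrank = lr, km = km,
                 hr = hr, tmb = tmb, tmb_correlation = corr,
                 mutation_frequencies = freq, mutation_contrasts = contrasts,
                 bivariate_survival = bisurv, gsea = gsea, ora = ora,
                 roc = roc, response_rates = rr, manifest = manifest,
                 out_dir = out_dir))
}
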