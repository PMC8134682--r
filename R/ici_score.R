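# ICI score construction: partition subtype-associated DEGs into opposing
# signatures A/B, reduce them with a shadow-feature (Boruta-style) random
# forest selector, and score each sample as PC1(signature A) - PC1(signature B).

#' Partition DEGs into signatures A and B
#'
#' Gene clusters are ordered from least to most immune-favorable
#' (`cluster_order`); each gene's expression is Spearman-correlated with that
#' ordered cluster rank. Positively associated genes form signature A,
#' negatively associated genes signature B; genes with |rho| below `tol`
#' (e.g. constant genes) are excluded.
#'
#' @param deg_expr Log2-scale expression matrix restricted to DEGs
#'   (genes x samples).
#' @param gene_cluster_labels Per-sample gene-cluster label.
#' @param cluster_order Cluster labels ordered by increasing immune
#'   favorability (defaults to alphabetical reverse, i.e. "A" most
#'   favorable last).
#' @param tol Association magnitude below which a gene is excluded.
#' @return List of class `signature_partition`: `genes_A`, `genes_B`,
#'   `stats` (`data.frame` of per-gene rho and assignment).
#' @export
assign_signatures <- function(deg_expr, gene_cluster_labels,
                              cluster_order = NULL, tol = 1e-12) {
  if (ncol(deg_expr) != length(gene_cluster_labels))
    stop("gene_cluster_labels must cover every sample")
  labels <- as.character(gene_cluster_labels)
  if (is.null(cluster_order)) cluster_order <- rev(sort(unique(labels)))
  if (!setequal(cluster_order, unique(labels)))
    stop("cluster_order must name exactly the observed clusters")
  rank_axis <- match(labels, cluster_order)
  X <- unclass(deg_expr)
  rho <- apply(X, 1L, function(x) {
    if (stats::sd(x) == 0) return(0)
    suppressWarnings(stats::cor(x, rank_axis, method = "spearman"))
  })
  rho[is.na(rho)] <- 0
  assignment <- ifelse(rho > tol, "A", ifelse(rho < -tol, "B", "excluded"))
  structure(list(genes_A = rownames(X)[assignment == "A"],
                 genes_B = rownames(X)[assignment == "B"],
                 stats = data.frame(gene = rownames(X), rho = rho,
                                    signature = assignment, row.names = NULL,
                                    stringsAsFactors = FALSE)),
            class = "signature_partition")
}

#' @export
print.signature_partition <- function(x, ...) {
  cat(sprintf("signature_partition: %d genes in A, %d in B, %d excluded\n",
              length(x$genes_A), length(x$genes_B),
              sum(x$stats$signature == "excluded")))
  invisible(x)
}

#' Shadow-feature (Boruta-style) gene selection
#'
#' Each iteration appends a shuffled "shadow" copy of every feature, fits a
#' random-forest classifier, and scores a feature a hit when its importance
#' exceeds the maximum shadow importance. After `n_iter` iterations each
#' feature's hit count is tested against Binomial(n_iter, 1/2) two-sidedly
#' with BH correction: significantly more hits than half confirms the
#' feature, significantly fewer rejects it, anything else stays tentative.
#'
#' @param x Samples x features numeric matrix (>= 20 samples).
#' @param y Class label per sample (>= 2 classes).
#' @param n_iter Number of shadow iterations.
#' @param alpha BH-adjusted significance level for the binomial decision.
#' @param num_trees Trees per random forest.
#' @param seed Integer seed.
#' @param include_tentative If `TRUE`, tentative features are returned too.
#' @return List of class `boruta_result`: `confirmed`, `tentative`,
#'   `rejected`, `hits`, `n_iter`, `selected` (confirmed, plus tentative if
#'   requested).
#' @export
boruta_select <- function(x, y, n_iter = 100, alpha = 0.05, num_trees = 100,
                          seed = 1, include_tentative = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 20) stop("need >= 20 samples for stable importance estimates")
  y <- factor(y)
  if (nlevels(y) < 2) stop("target must have at least 2 classes")
  p <- ncol(x)
  feat <- colnames(x)
  if (is.null(feat)) feat <- paste0("f", seq_len(p))
  hits <- stats::setNames(integer(p), feat)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      shadow <- apply(x, 2L, sample)
      colnames(shadow) <- paste0(".shadow", seq_len(p))
      df <- data.frame(cbind(x, shadow))
      names(df) <- c(feat, colnames(shadow))
      fit <- ranger::ranger(x = df, y = y, num.trees = num_trees,
                            importance = "impurity",
                            num.threads = 1L,
                            seed = sample.int(.Machine$integer.max, 1L))
      imp <- fit$variable.importance
      max_shadow <- max(imp[paste0(".shadow", seq_len(p))])
      hits <- hits + as.integer(imp[feat] > max_shadow)
    }
  })
  p_two <- vapply(hits, function(h) {
    min(1, 2 * min(stats::pbinom(h, n_iter, 0.5),
                   stats::pbinom(h - 1L, n_iter, 0.5, lower.tail = FALSE)))
  }, 0)
  p_adj <- bh_adjust(p_two)
  confirmed <- feat[p_adj < alpha & hits > n_iter / 2]
  rejected <- feat[p_adj < alpha & hits < n_iter / 2]
  tentative <- setdiff(feat, c(confirmed, rejected))
  structure(list(confirmed = confirmed, tentative = tentative,
                 rejected = rejected, hits = hits, n_iter = n_iter,
                 selected = if (include_tentative) c(confirmed, tentative)
                            else confirmed),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("boruta_result: %d confirmed, %d tentative, %d rejected (n_iter=%d)\n",
              length(x$confirmed), length(x$tentative), length(x$rejected),
              x$n_iter))
  invisible(x)
}

#' First-principal-component signature score
#'
#' Genes are z-scored across samples (zero-variance genes dropped with a
#' warning); the score is each sample's projection on the first principal
#' component, with the sign fixed so the score correlates positively with
#' the mean z-scored expression of the gene subset. The anchor makes the
#' score invariant to the arbitrary sign of the eigenvector.
#'
#' @param expr_subset Expression matrix restricted to the signature genes
#'   (>= 2 genes, >= 3 samples).
#' @return Named numeric vector of per-sample scores, with attribute
#'   `var_explained` (PC1's share of total variance).
#' @export
pc1_score <- function(expr_subset) {
  X <- unclass(expr_subset)
  if (ncol(X) < 3) stop("need >= 3 samples")
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s)")
    X <- X[sds > 0, , drop = FALSE]
  }
  if (nrow(X) < 2) stop("fewer than 2 non-constant genes; cannot score")
  Z <- t(scale(t(X)))
  pc <- stats::prcomp(t(Z), center = FALSE, scale. = FALSE)
  score <- pc$x[, 1L]
  anchor <- colMeans(Z)
  if (stats::cor(score, anchor) < 0) score <- -score
  attr(score, "var_explained") <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  score
}

#' Compute per-sample ICI scores
#'
#' `ici_score = PC1(signature A) - PC1(signature B)`, each term the
#' sign-anchored first-principal-component score of that signature's gene
#' block. If one signature has no genes present, its term is 0 with a
#' warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param partition A [assign_signatures] result (or list with `genes_A`,
#'   `genes_B`).
#' @return `data.frame` with `sample_id`, `pc1a`, `pc1b`, `ici_score`.
#' @export
compute_ici_score <- function(expr, partition) {
  ga <- intersect(partition$genes_A, rownames(expr))
  gb <- intersect(partition$genes_B, rownames(expr))
  if (length(ga) == 0 && length(gb) == 0)
    stop("no signature genes present in the expression matrix")
  zero <- stats::setNames(rep(0, ncol(expr)), colnames(expr))
  pc1a <- if (length(ga) >= 2) pc1_score(expr[ga, , drop = FALSE]) else {
    if (length(partition$genes_A)) warning("signature A empty or too small; term set to 0")
    zero
  }
  pc1b <- if (length(gb) >= 2) pc1_score(expr[gb, , drop = FALSE]) else {
    if (length(partition$genes_B)) warning("signature B empty or too small; term set to 0")
    zero
  }
  data.frame(sample_id = colnames(expr),
             pc1a = as.numeric(pc1a)[match(colnames(expr), names(pc1a))],
             pc1b = as.numeric(pc1b)[match(colnames(expr), names(pc1b))],
             ici_score = as.numeric(pc1a - pc1b),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign high/low score groups at a cutoff
#'
#' @param score_table Output of [compute_ici_score].
#' @param cutoff Numeric cutoff; scores strictly above it are "high".
#' @return The table with `group` and `cutoff_used` columns added.
#' @export
assign_score_groups <- function(score_table, cutoff) {
  score_table$group <- ifelse(score_table$ici_score > cutoff, "high", "low")
  score_table$cutoff_used <- cutoff
  score_table
}
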