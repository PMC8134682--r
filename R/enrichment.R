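# Preranked gene set enrichment (weighted running-sum ES, gene-label
# permutation null, pooled-null FDR) and hypergeometric over-representation
# against user-supplied gene sets.

# Weighted Kolmogorov-Smirnov running-sum enrichment score for a set of hit
# positions within a ranked list. Returns the signed extremum and its index.
gsea_running_es <- function(scores_sorted, hit_idx, weight = 1) {
  n <- length(scores_sorted)
  nh <- length(hit_idx)
  inc <- numeric(n)
  w <- abs(scores_sorted[hit_idx])^weight
  if (sum(w) == 0) w <- rep(1, nh)  # all-zero scores: fall back to unweighted
  inc[hit_idx] <- w / sum(w)
  dec <- rep(1 / (n - nh), n)
  dec[hit_idx] <- 0
  run <- cumsum(inc - dec)
  i_max <- which.max(run); i_min <- which.min(run)
  if (run[i_max] >= -run[i_min]) list(es = run[i_max], peak = i_max)
  else list(es = run[i_min], peak = i_min)
}

#' Preranked gene set enrichment analysis
#'
#' Genes are sorted by decreasing ranking metric. The running sum steps up at
#' set members proportionally to `|score|^weight` (normalized to 1 in total)
#' and down by `1/(N - |S|)` elsewhere; the enrichment score (ES) is the
#' signed extremum. The null distribution comes from gene-label permutations
#' (random sets of the same size); NES divides ES by the mean magnitude of
#' same-sign null scores, nominal p is the same-sign null tail fraction, and
#' FDR q follows the standard pooled positive/negative null procedure. The
#' leading edge holds the set members at or before (after, for negative ES)
#' the running-sum peak.
#'
#' @param ranks Named numeric vector (gene -> ranking metric, finite).
#' @param gene_sets Named list of gene id vectors; sets are filtered to
#'   `min_size <= |set in ranks| <= max_size`.
#' @param n_perm Number of permutations.
#' @param weight Hit-weighting exponent (0 = classic KS).
#' @param seed Integer seed for the permutation stream.
#' @param min_size,max_size Set size filter after intersection.
#' @return `data.frame` of class `gsea_result`: `set`, `size`, `es`, `nes`,
#'   `p`, `fdr_q`, `leading_edge` (comma-separated genes).
#' @export
preranked_gsea <- function(ranks, gene_sets, n_perm = 1000, weight = 1,
                           seed = 1, min_size = 5, max_size = 500) {
  if (!all(is.finite(ranks))) stop("ranking metric must be finite")
  ord <- order(ranks, decreasing = TRUE)
  genes <- names(ranks)[ord]
  scores <- unname(ranks[ord])
  n <- length(genes)
  sizes <- vapply(gene_sets, function(s) length(intersect(s, genes)), 0L)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep)) {
    warning("no gene set survives the size filter")
    return(structure(data.frame(set = character(0), size = integer(0),
                                es = numeric(0), nes = numeric(0),
                                p = numeric(0), fdr_q = numeric(0),
                                leading_edge = character(0),
                                stringsAsFactors = FALSE),
                     class = c("gsea_result", "data.frame")))
  }
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]

  obs <- lapply(gene_sets, function(s) {
    hit_idx <- which(genes %in% s)
    r <- gsea_running_es(scores, hit_idx, weight)
    le <- if (r$es >= 0) genes[intersect(hit_idx, seq_len(r$peak))]
          else genes[hit_idx[hit_idx >= r$peak]]
    list(es = r$es, leading_edge = le)
  })
  es <- vapply(obs, `[[`, 0, "es")

  # one null matrix per distinct set size
  null_by_size <- list()
  with_seed(seed, {
    for (sz in unique(sizes)) {
      null_by_size[[as.character(sz)]] <- vapply(seq_len(n_perm), function(b) {
        gsea_running_es(scores, sort(sample.int(n, sz)), weight)$es
      }, 0)
    }
  })

  nes <- p <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nul <- null_by_size[[as.character(sizes[i])]]
    same <- if (es[i] >= 0) nul[nul >= 0] else nul[nul < 0]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(nul))
    nes[i] <- es[i] / denom
    p[i] <- if (length(same) == 0) 1 / n_perm else
      (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
    pos <- nul[nul >= 0]; neg <- nul[nul < 0]
    null_nes[[i]] <- c(if (length(pos)) pos / mean(abs(pos)),
                       if (length(neg)) neg / mean(abs(neg)))
  }
  pooled_null <- unlist(null_nes)
  fdr_q <- vapply(seq_along(nes), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pooled_null >= nes[i])
      den <- mean(nes >= nes[i])
    } else {
      num <- mean(pooled_null <= nes[i])
      den <- mean(nes <= nes[i])
    }
    min(1, num / max(den, 1e-12))
  }, 0)

  structure(data.frame(set = names(gene_sets), size = sizes, es = es,
                       nes = nes, p = p, fdr_q = fdr_q,
                       leading_edge = vapply(obs, function(o)
                         paste(o$leading_edge, collapse = ","), ""),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("gsea_result", "data.frame"))
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value for the overlap between a query gene
#' list and each gene set, within a stated universe; BH adjustment across
#' sets.
#'
#' @param query_genes Character vector (must lie within `universe`).
#' @param gene_sets Named list of gene id vectors.
#' @param universe Character vector of all testable genes (non-empty).
#' @return `data.frame`: `set`, `set_size` (in universe), `overlap`, `p`,
#'   `q_bh`.
#' @export
hypergeometric_ora <- function(query_genes, gene_sets, universe) {
  if (length(universe) == 0) stop("universe must be non-empty")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe))
    stop("query genes must be a subset of the universe")
  n_u <- length(universe)
  n_q <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(query_genes, s))
    p <- stats::phyper(k - 1, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- bh_adjust(out$p)
  out
}
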