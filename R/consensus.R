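# Resampling-based consensus clustering with delta-area selection of k.
# Used twice by the pipeline: on cell fractions (immune subtypes) and on DEG
# expression (gene clusters).

#' Consensus clustering with subsampling
#'
#' For each of `reps` resamples, a fraction of items is drawn without
#' replacement and clustered at every k in `k_range` with the base method
#' (hierarchical clustering with Ward linkage on Euclidean distance by
#' default, or k-means). The consensus value for an item pair is the number
#' of times they co-clustered divided by the number of times they were
#' co-sampled. Final labels at each k come from hierarchical clustering of
#' `1 - consensus`. `chosen_k` comes from the delta-area criterion: the
#' relative change of the area under the consensus CDF is computed per k
#' (for the smallest k it is the area itself), and the elbow — the k after
#' which that relative gain collapses, located as the largest ratio of
#' consecutive delta-areas — is selected. The largest k in the range can
#' therefore never be chosen automatically; pin k explicitly to use it.
#'
#' @param data Numeric matrix, items in rows, features in columns.
#' @param k_range Candidate cluster counts (all >= 2, max < number of items).
#' @param reps Number of subsampling repetitions (>= 10).
#' @param subsample Fraction of items drawn per repetition.
#' @param base_method `"hclust"` (Ward) or `"kmeans"`.
#' @param seed Integer seed; results are a pure function of it.
#' @return List of class `consensus_result`: `consensus` (list of items x
#'   items matrices per k), `labels` (list of integer label vectors per k),
#'   `cdf_area`, `delta_area`, `chosen_k`, `never_cosampled` (count of item
#'   pairs with no co-sampling information), plus the call parameters.
#' @export
consensus_cluster <- function(data, k_range = 2:6, reps = 1000,
                              subsample = 0.8,
                              base_method = c("hclust", "kmeans"), seed = 1) {
  base_method <- match.arg(base_method)
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 10) stop("need at least 10 items to cluster")
  if (reps < 10) stop("reps must be >= 10")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("k_range entries must be >= 2")
  if (max(k_range) >= n) stop("max(k_range) must be below the number of items")
  items <- rownames(data)
  if (is.null(items)) items <- paste0("item", seq_len(n))
  m_sub <- max(2L, floor(subsample * n))

  co_sample <- matrix(0, n, n)
  co_cluster <- stats::setNames(
    lapply(k_range, function(k) matrix(0, n, n)), as.character(k_range))
  with_seed(seed, {
    for (b in seq_len(reps)) {
      idx <- sort(sample.int(n, m_sub))
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
      sub <- data[idx, , drop = FALSE]
      hc <- if (base_method == "hclust")
        stats::hclust(stats::dist(sub), method = "ward.D2") else NULL
      for (k in k_range) {
        cl <- if (base_method == "hclust") stats::cutree(hc, k = k)
        else stats::kmeans(sub, centers = k, nstart = 1)$cluster
        same <- outer(cl, cl, "==")
        kk <- as.character(k)
        co_cluster[[kk]][idx, idx] <- co_cluster[[kk]][idx, idx] + same
      }
    }
  })

  never <- (sum(co_sample == 0) - sum(diag(co_sample) == 0)) / 2
  consensus <- lapply(co_cluster, function(cc) {
    M <- cc / pmax(co_sample, 1)
    M[co_sample == 0] <- NA_real_
    diag(M) <- 1
    dimnames(M) <- list(items, items)
    M
  })

  labels <- lapply(seq_along(k_range), function(i) {
    M <- consensus[[i]]
    M[is.na(M)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - M), method = "ward.D2")
    stats::setNames(stats::cutree(hc, k = k_range[i]), items)
  })
  names(labels) <- as.character(k_range)

  cdf_area <- vapply(consensus, function(M) {
    v <- M[upper.tri(M)]
    v <- v[!is.na(v)]
    consensus_cdf_area(v)
  }, 0)
  delta_area <- diff(c(0, cdf_area)) / c(1, utils::head(cdf_area, -1))
  names(delta_area) <- names(cdf_area)
  # elbow of the delta-area curve: the k after which the relative area gain
  # collapses, i.e. the largest drop ratio delta(k)/delta(k+1)
  if (length(k_range) == 1L) {
    chosen_k <- k_range
  } else {
    nxt <- delta_area[-1L]
    ratio <- ifelse(nxt > 0, utils::head(delta_area, -1L) / nxt, Inf)
    chosen_k <- k_range[which.max(ratio)]
  }

  structure(list(consensus = consensus, labels = labels,
                 cdf_area = cdf_area, delta_area = delta_area,
                 chosen_k = chosen_k, k_range = k_range, reps = reps,
                 subsample = subsample, base_method = base_method,
                 seed = seed, never_cosampled = never),
            class = "consensus_result")
}

# Area under the empirical CDF of consensus values over [0, 1].
consensus_cdf_area <- function(v) {
  xs <- sort(unique(c(v, 1)))
  cdf <- stats::ecdf(v)
  sum(diff(c(0, xs)) * cdf(c(0, utils::head(xs, -1)))) + 0
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d items, reps=%d, k in {%s}\n",
              nrow(x$consensus[[1]]), x$reps,
              paste(x$k_range, collapse = ",")))
  cat(sprintf("chosen_k = %d (delta-area: %s)\n", x$chosen_k,
              paste(sprintf("%s=%.3f", names(x$delta_area), x$delta_area),
                    collapse = " ")))
  invisible(x)
}

#' Canonicalize cluster labels by a per-item score
#'
#' Relabels integer clusters as letters ordered by decreasing mean score, so
#' cluster "A" always has the highest mean immune level regardless of the
#' arbitrary integer labels a clustering run produced.
#'
#' @param labels Integer or character cluster labels, named by item.
#' @param score Numeric vector aligned with `labels`.
#' @param decreasing Order of mean score mapped to A, B, C, ...
#' @return Named character vector of letters.
#' @export
canonicalize_clusters <- function(labels, score, decreasing = TRUE) {
  stopifnot(length(labels) == length(score))
  means <- tapply(score, labels, mean)
  ord <- names(sort(means, decreasing = decreasing))
  map <- stats::setNames(LETTERS[seq_along(ord)], ord)
  stats::setNames(unname(map[as.character(labels)]), names(labels))
}

#' Per-cluster cell-fraction summary with Kruskal-Wallis tests
#'
#' For every cell type, reports median and IQR within each cluster and a
#' Kruskal-Wallis p-value for differences across clusters. Clusters with
#' fewer than 2 members make the test undefined; p is reported as `NA`.
#'
#' @param fractions Samples x cell types matrix.
#' @param labels Cluster labels aligned with the rows of `fractions`.
#' @return `data.frame` with one row per (cell type, cluster) plus a
#'   per-cell-type `kw_p` column (repeated within cell type).
#' @export
cluster_fraction_summary <- function(fractions, labels) {
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != length(labels))
    stop("labels must cover every sample")
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  small <- any(table(labels) < 2)
  out <- list()
  for (ct in colnames(fractions)) {
    x <- fractions[, ct]
    p <- if (small) NA_real_ else
      suppressWarnings(stats::kruskal.test(x, factor(labels))$p.value)
    for (cl in clusters) {
      xi <- x[labels == cl]
      out[[length(out) + 1L]] <- data.frame(
        cell_type = ct, cluster = cl, n = length(xi),
        median = stats::median(xi),
        q1 = unname(stats::quantile(xi, 0.25)),
        q3 = unname(stats::quantile(xi, 0.75)),
        kw_p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
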