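# Moderated two-sample t-tests with empirical-Bayes variance shrinkage, and
# DEG selection across immune subtypes (one-vs-rest contrasts, fold-change +
# BH-adjusted p thresholds).

# Solve trigamma(y) = x by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# Fit the scaled-F hyperparameters (d0, s0^2) of the gene-wise sample
# variances by moment matching on the log scale.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2)
  s2 <- s2[ok]
  s2 <- pmax(s2, 1e-12)  # guard exact zeros before taking logs
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  rhs <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    # no excess dispersion beyond chi-square sampling noise: infinite prior
    # df, prior variance estimated by the mean of the gene-wise variances
    list(d0 = Inf, s0_sq = mean(s2))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    list(d0 = d0, s0_sq = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Moderated two-sample t-test
#'
#' Per gene, the log2 fold change is the mean difference between the contrast
#' group and the rest; the residual variance is shrunk toward a prior fitted
#' by matching moments of the scaled-F distribution of the gene-wise
#' variances (posterior variance `(d0*s0^2 + d*s^2)/(d0 + d)`); the
#' moderated t has `d0 + d` degrees of freedom. With `d0 = Inf` the
#' statistic reduces to a z-statistic against the pooled prior variance;
#' with `d0 = 0` (forced via `prior`) it is the ordinary two-sample t.
#'
#' @param m Log2-scale [expr_matrix] (or plain matrix).
#' @param group_labels Vector of group labels aligned with columns of `m`.
#' @param contrast The label tested against the rest (>= 2 samples per side).
#' @param prior Optional list `(d0, s0_sq)` overriding the fitted prior
#'   (useful for limiting-case checks).
#' @return `data.frame` with `gene`, `log2_fc`, `t`, `df_total`, `p`.
#' @export
moderated_t_test <- function(m, group_labels, contrast, prior = NULL) {
  X <- unclass(m)
  g1 <- group_labels == contrast
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 samples on each side of the contrast")
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, g2, drop = FALSE])
  fc <- m1 - m2
  ss1 <- rowSums((X[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, g2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  if (is.null(prior)) prior <- fit_variance_prior(s2, df)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  post_var <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + df * s2) / (d0 + df)
  se <- sqrt(post_var * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, fc / se, 0)
  df_total <- d0 + df
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), df = df_total)
  p[fc == 0 & s2 == 0] <- 1  # constant genes carry no evidence
  data.frame(gene = rownames(X), log2_fc = fc, t = tstat,
             df_total = df_total, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1 (delegates to [stats::p.adjust]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Select differentially expressed genes across clusters
#'
#' Runs a one-vs-rest moderated t-test for every cluster; p-values are
#' BH-adjusted within each contrast. A gene is a DEG if in at least one
#' contrast `|log2 FC| > fc_threshold` and adjusted p `< alpha`; the union is
#' deduplicated keeping each gene's best (smallest adjusted p) contrast.
#'
#' @param m Log2-scale expression matrix.
#' @param cluster_labels Cluster label per sample (>= 2 clusters).
#' @param fc_threshold Fold-change threshold. With `fc_scale = "log2"`
#'   (default, the conventional reading of "absolute fold-change > 1") the
#'   threshold applies to `|log2 FC|`; with `"linear"` it applies to the
#'   linear fold change `2^|log2 FC|`.
#' @param alpha Adjusted-p threshold.
#' @param fc_scale `"log2"` or `"linear"` (see `fc_threshold`).
#' @return `data.frame` with `gene`, `contrast`, `log2_fc`, `t`, `p`,
#'   `p_adj_bh`, `passes_threshold`; one row per gene x contrast, with
#'   attribute `deg_genes` (the union list) attached.
#' @export
select_degs <- function(m, cluster_labels, fc_threshold = 1.0, alpha = 0.05,
                        fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  clusters <- sort(unique(as.character(cluster_labels)))
  if (length(clusters) < 2) stop("need at least 2 clusters for contrasts")
  res <- lapply(clusters, function(cl) {
    tt <- moderated_t_test(m, cluster_labels, cl)
    tt$contrast <- paste0(cl, "_vs_rest")
    tt$p_adj_bh <- bh_adjust(tt$p)
    fc_ok <- if (fc_scale == "log2") abs(tt$log2_fc) > fc_threshold
             else 2^abs(tt$log2_fc) > fc_threshold
    tt$passes_threshold <- fc_ok & tt$p_adj_bh < alpha
    tt
  })
  all_res <- do.call(rbind, res)
  deg <- unique(all_res$gene[all_res$passes_threshold])
  # best contrast per DEG
  hits <- all_res[all_res$passes_threshold, ]
  hits <- hits[order(hits$gene, hits$p_adj_bh), ]
  best <- hits[!duplicated(hits$gene), ]
  attr(all_res, "deg_genes") <- deg
  attr(all_res, "best_contrast") <- best
  all_res
}
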