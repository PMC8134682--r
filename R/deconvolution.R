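# Cell-fraction deconvolution (nu-SVR against a reference signature, the
# CIBERSORT scheme) and rank-based single-sample enrichment scores
# (ESTIMATE-style immune/stromal scoring).

#' Deconvolve bulk expression into immune cell fractions
#'
#' For each bulk sample: the genes shared with the signature matrix are
#' z-scored in both the bulk column and each signature column; a linear
#' nu-support-vector regression of the bulk on the signature is fitted for
#' each `nu` in `nu_grid`; the fit with the lowest root-mean-square
#' reconstruction error is kept; negative coefficients are clipped to zero
#' and the rest normalized to sum to one. An optional permutation p-value
#' measures how often gene-shuffled bulk vectors achieve the observed
#' reconstruction correlation.
#'
#' @param bulk Linear-scale [expr_matrix] of mixtures (genes x samples).
#' @param sig Linear-scale [expr_matrix] signature (genes x cell types).
#' @param nu_grid Candidate `nu` values for the SVR.
#' @param n_permutations Permutations for the p-value (0 disables it).
#' @param seed Seed for the permutation stream.
#' @param quantile_normalize If `TRUE`, quantile-normalize the bulk columns
#'   to a common distribution first (the original array-mode preprocessing;
#'   off by default).
#' @return List of class `cell_fractions`: `fractions` (samples x cell types
#'   matrix, rows sum to 1) and `diagnostics` (`data.frame` with per-sample
#'   `rmse`, `corr`, `p_value`, `nu`).
#' @export
svr_deconvolve <- function(bulk, sig, nu_grid = c(0.25, 0.5, 0.75),
                           n_permutations = 0, seed = 1,
                           quantile_normalize = FALSE) {
  if (expr_scale(bulk) != "linear" || expr_scale(sig) != "linear")
    stop("deconvolution expects linear-scale bulk and signature matrices")
  shared <- intersect(rownames(sig), rownames(bulk))
  if (length(shared) == 0) stop("no genes shared between bulk and signature")
  if (length(shared) < 0.5 * nrow(sig))
    warning(sprintf("only %d/%d signature genes found in bulk matrix",
                    length(shared), nrow(sig)))
  X <- unclass(sig)[shared, , drop = FALSE]
  Y <- unclass(bulk)[shared, , drop = FALSE]
  if (qr(X)$rank < ncol(X))
    warning("signature matrix is rank-deficient; fractions may be unstable")
  if (quantile_normalize) Y <- quantile_normalize_columns(Y)
  Xz <- scale(X)
  types <- colnames(sig)
  samples <- colnames(bulk)
  fr <- matrix(0, length(samples), length(types),
               dimnames = list(samples, types))
  diag_df <- data.frame(sample_id = samples, rmse = NA_real_, corr = NA_real_,
                        p_value = NA_real_, nu = NA_real_,
                        stringsAsFactors = FALSE)

  fit_one <- function(y) {
    yz <- as.numeric(scale(y))
    best <- NULL
    for (nu in nu_grid) {
      model <- e1071::svm(x = Xz, y = yz, type = "nu-regression",
                          kernel = "linear", nu = nu, scale = FALSE)
      w <- as.numeric(t(model$coefs) %*% model$SV)
      w[w < 0] <- 0
      f <- if (sum(w) > 0) w / sum(w) else w
      recon <- as.numeric(Xz %*% f)
      rmse <- sqrt(mean((recon - yz)^2))
      if (is.null(best) || rmse < best$rmse)
        best <- list(f = f, rmse = rmse,
                     corr = if (stats::sd(recon) > 0)
                       stats::cor(recon, yz) else 0,
                     nu = nu)
    }
    best
  }

  perm_corrs <- NULL
  if (n_permutations > 0) {
    pool <- as.numeric(Y)
    with_seed(seed, {
      perm_corrs <- vapply(seq_len(n_permutations), function(b) {
        fit_one(sample(pool, length(shared)))$corr
      }, 0)
    })
  }
  for (j in seq_along(samples)) {
    fit <- fit_one(Y[, j])
    fr[j, ] <- fit$f
    diag_df$rmse[j] <- fit$rmse
    diag_df$corr[j] <- fit$corr
    diag_df$nu[j] <- fit$nu
    if (!is.null(perm_corrs))
      diag_df$p_value[j] <- mean(perm_corrs >= fit$corr)
  }
  structure(list(fractions = fr, diagnostics = diag_df,
                 n_permutations = n_permutations, seed = seed),
            class = "cell_fractions")
}

#' @export
print.cell_fractions <- function(x, ...) {
  cat(sprintf("cell_fractions: %d samples x %d cell types\n",
              nrow(x$fractions), ncol(x$fractions)))
  cat(sprintf("mean reconstruction RMSE %.3f, mean correlation %.3f\n",
              mean(x$diagnostics$rmse), mean(x$diagnostics$corr)))
  invisible(x)
}

quantile_normalize_columns <- function(Y) {
  ranks <- apply(Y, 2L, rank, ties.method = "average")
  ref <- rowMeans(apply(Y, 2L, sort))
  out <- apply(ranks, 2L, function(r) stats::approx(seq_along(ref), ref, r)$y)
  dimnames(out) <- dimnames(Y)
  out
}

#' Single-sample gene set enrichment score
#'
#' Rank-based running-sum score per sample: genes are ordered by decreasing
#' expression (average ranks for ties); walking down the list, the in-set
#' ECDF steps up in proportion to `rank^alpha` and the out-of-set ECDF steps
#' up uniformly; the score is the sum of (ECDF_in - ECDF_out) over all
#' positions (integrated-difference form). Being rank-based, the score is
#' invariant to any strictly monotone transform of a sample's expression.
#' When the set covers every gene there is no out-of-set mass and the score
#' is defined as 0.
#'
#' @param m [expr_matrix] (any scale; only ranks are used).
#' @param gene_set Character vector of gene ids (>= 2 present in `m`).
#' @param alpha Rank-weighting exponent (0 = unweighted KS).
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(m, gene_set, alpha = 0.25) {
  present <- intersect(gene_set, rownames(m))
  if (length(present) == 0) stop("gene set shares no genes with the matrix")
  if (length(present) < 2)
    stop("need >= 2 gene-set genes present in the matrix")
  n <- nrow(m)
  in_set <- rownames(m) %in% present
  n_out <- n - sum(in_set)
  apply(unclass(m), 2L, function(x) {
    if (n_out == 0) return(0)
    r <- rank(x, ties.method = "average")  # ascending: top gene has rank n
    ord <- order(x, decreasing = TRUE)
    hit <- in_set[ord]
    w <- r[ord]^alpha
    w[!hit] <- 0
    ecdf_in <- cumsum(w) / sum(w)
    ecdf_out <- cumsum(!hit) / n_out
    sum(ecdf_in - ecdf_out)
  })
}

#' ESTIMATE-style immune, stromal and combined scores
#'
#' Applies [ssgsea_score] to an immune and a stromal marker set;
#' `estimate_score` is their sum.
#'
#' @param m [expr_matrix].
#' @param immune_set,stromal_set Character vectors of marker genes.
#' @param alpha Rank-weighting exponent passed to [ssgsea_score].
#' @return `data.frame` with `sample_id`, `immune_score`, `stromal_score`,
#'   `estimate_score`.
#' @export
estimate_scores <- function(m, immune_set, stromal_set, alpha = 0.25) {
  imm <- ssgsea_score(m, immune_set, alpha)
  str <- ssgsea_score(m, stromal_set, alpha)
  data.frame(sample_id = colnames(m), immune_score = as.numeric(imm),
             stromal_score = as.numeric(str),
             estimate_score = as.numeric(imm + str),
             stringsAsFactors = FALSE)
}
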