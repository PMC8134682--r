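# Synthetic cohort generator. Emulates the statistical structure the pipeline
# assumes: bulk expression as convex mixtures of cell-type signature profiles
# plus multiplicative noise, survival hazard linked to latent immune content,
# group-dependent mutation rates, and proportional-odds therapy response.

#' Default 22 immune cell type labels
#'
#' LM22-style phenotype labels used by the synthetic signature matrix.
#' @export
default_cell_types <- function() {
  c("B_naive", "B_memory", "Plasma_cells", "CD8_T", "CD4_T_naive",
    "CD4_T_memory_resting", "CD4_T_memory_activated", "T_follicular_helper",
    "Treg", "T_gamma_delta", "NK_resting", "NK_activated", "Monocytes",
    "Macrophage_M0", "Macrophage_M1", "Macrophage_M2", "DC_resting",
    "DC_activated", "Mast_resting", "Mast_activated", "Eosinophils",
    "Neutrophils")
}

# Cell types treated as anti-tumor ("cytotoxic") when computing the latent
# immune level that drives survival and response in the generator.
CYTOTOXIC_TYPES <- c("CD8_T", "NK_activated", "CD4_T_memory_activated",
                     "T_follicular_helper")

#' Generate a block-structured cell-type signature matrix
#'
#' Each cell type gets `markers_per_type` marker genes expressed at
#' `expression_level` in its own column and `background_level` in all other
#' columns, with multiplicative log-normal jitter. The result mimics an
#' LM22-style reference: full column rank, marker-dominated.
#'
#' @param n_cell_types Number of cell types (>= 2). When 22, columns are
#'   named by [default_cell_types()].
#' @param markers_per_type Marker genes per cell type (>= 1).
#' @param expression_level,background_level Marker / off-target expression
#'   levels (linear scale, `expression_level > 0`,
#'   `background_level >= 0`).
#' @param jitter_sd SD of the log-normal jitter (log scale).
#' @param seed Integer seed; the matrix is a pure function of it.
#' @return Linear-scale [expr_matrix], genes x cell types.
#' @export
make_signature_matrix <- function(n_cell_types = 22, markers_per_type = 10,
                                  expression_level = 100, background_level = 1,
                                  jitter_sd = 0.1, seed = 1) {
  if (n_cell_types < 2) stop("n_cell_types must be >= 2")
  if (markers_per_type < 1) stop("markers_per_type must be >= 1")
  if (expression_level <= 0) stop("expression_level must be positive")
  if (background_level < 0) stop("background_level must be non-negative")
  if (expression_level <= background_level)
    stop("expression_level must exceed background_level")
  types <- if (n_cell_types == 22) default_cell_types() else
    paste0("CT", seq_len(n_cell_types))
  genes <- as.vector(t(outer(types, seq_len(markers_per_type),
                             function(tp, j) paste0(tp, ".M", j))))
  n_genes <- n_cell_types * markers_per_type
  base <- matrix(background_level, n_genes, n_cell_types,
                 dimnames = list(genes, types))
  for (k in seq_len(n_cell_types)) {
    rows <- (k - 1L) * markers_per_type + seq_len(markers_per_type)
    base[rows, k] <- expression_level
  }
  with_seed(seed, {
    jitter <- matrix(exp(stats::rnorm(length(base), 0, jitter_sd)),
                     n_genes, n_cell_types)
  })
  expr_matrix(base * jitter, "linear")
}

# Dirichlet sampler via independent gammas.
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stop("Dirichlet alpha entries must be > 0")
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

# Run `code` under a local RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Default per-subtype Dirichlet concentrations
#'
#' Encodes three immune phenotypes as relative concentration weights over the
#' 22 default cell types: subtype A (immune-inflamed; high CD8 T, activated
#' NK, activated memory CD4, Tfh), subtype B (immune-desert; dominated by M0
#' macrophages, activated mast and resting NK, low everything else) and
#' subtype C (immune-excluded; high naive/memory B, Treg, M1/M2 macrophages).
#'
#' @param cell_types Cell type labels (defaults to the 22 standard labels).
#' @return Named list of three alpha vectors.
#' @export
default_subtype_alphas <- function(cell_types = default_cell_types()) {
  base <- stats::setNames(rep(1, length(cell_types)), cell_types)
  a <- base
  a[c("CD8_T", "NK_activated", "CD4_T_memory_activated",
      "T_follicular_helper")] <- 8
  b <- stats::setNames(rep(0.4, length(cell_types)), cell_types)
  b[c("Macrophage_M0", "Mast_activated", "NK_resting")] <- 6
  c_ <- base
  c_[c("B_naive", "B_memory", "Treg", "Macrophage_M1", "Macrophage_M2")] <- 8
  list(A = a, B = b, C = c_)
}

#' Simulate bulk mixtures from a signature matrix
#'
#' Sample `j` of subtype `s` draws cell fractions from
#' `Dirichlet(alpha_s)`; its bulk column is `sig %*% f` multiplied gene-wise
#' by `exp(N(0, noise_sd^2))`. Ground-truth fractions and subtype labels are
#' returned alongside the expression.
#'
#' @param sig Signature [expr_matrix] (genes x cell types).
#' @param n_samples Number of bulk samples.
#' @param alphas Named list of Dirichlet alpha vectors, one per planted
#'   subtype, each of length `ncol(sig)`.
#' @param noise_sd SD of the multiplicative log-normal noise.
#' @param seed Integer seed.
#' @return List with `expression` ([expr_matrix]), `fractions`
#'   (samples x cell types matrix, rows sum to 1) and `subtype` (named
#'   character vector).
#' @export
simulate_mixtures <- function(sig, n_samples, alphas = default_subtype_alphas(),
                              noise_sd = 0.2, seed = 1) {
  stopifnot(is.list(alphas), length(alphas) >= 1)
  for (a in alphas) {
    if (length(a) != ncol(sig))
      stop("each alpha vector must have one entry per signature cell type")
    if (any(a <= 0)) stop("Dirichlet alpha entries must be > 0")
  }
  samples <- sprintf("S%03d", seq_len(n_samples))
  with_seed(seed, {
    subtype <- sample(names(alphas), n_samples, replace = TRUE)
    fr <- matrix(NA_real_, n_samples, ncol(sig),
                 dimnames = list(samples, colnames(sig)))
    for (s in names(alphas)) {
      idx <- which(subtype == s)
      if (length(idx)) fr[idx, ] <- rdirichlet(length(idx), alphas[[s]])
    }
    bulk <- unclass(sig) %*% t(fr)
    if (noise_sd > 0)
      bulk <- bulk * exp(matrix(stats::rnorm(length(bulk), 0, noise_sd),
                                nrow(bulk), ncol(bulk)))
  })
  colnames(bulk) <- samples
  list(expression = expr_matrix(bulk, "linear"),
       fractions = fr,
       subtype = stats::setNames(subtype, samples))
}

#' Simulate survival linked to a per-sample score
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr_per_unit * score)`, the simplest model
#' satisfying proportional hazards (so a Cox fit on the truth recovers
#' `log_hr_per_unit` in expectation). With probability `censor_rate` a sample
#' is censored at a uniform time before its event.
#'
#' @param score Named numeric vector (names = sample ids).
#' @param baseline_hazard Events per time unit at score 0 (> 0).
#' @param log_hr_per_unit Log hazard ratio per unit of score.
#' @param censor_rate Probability of censoring, in `[0, 1)`.
#' @param seed Integer seed.
#' @param time_unit Unit label recorded on the output.
#' @return Clinical `data.frame` (`sample_id`, `os_time`, `os_event`).
#' @export
simulate_survival <- function(score, baseline_hazard = 0.02,
                              log_hr_per_unit = -1, censor_rate = 0.3,
                              seed = 1, time_unit = "months") {
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  n <- length(score)
  with_seed(seed, {
    hazard <- baseline_hazard * exp(log_hr_per_unit * score)
    t_event <- stats::rexp(n, rate = hazard)
    censored <- stats::runif(n) < censor_rate
    t_obs <- ifelse(censored, stats::runif(n) * t_event, t_event)
  })
  out <- data.frame(sample_id = names(score),
                    os_time = as.numeric(t_obs),
                    os_event = as.numeric(!censored),
                    stringsAsFactors = FALSE)
  attr(out, "time_unit") <- time_unit
  out
}

#' Simulate a somatic mutation table
#'
#' Per sample, the non-synonymous background burden is Poisson with its
#' group's mean, spread over anonymous passenger genes; each listed driver
#' gene additionally mutates with a group-dependent Bernoulli probability
#' (`base_rate` in the reference group, odds-scaled in `enriched_group`).
#' Roughly 30% extra silent records are added so classification filtering is
#' exercised.
#'
#' @param groups Named character/factor vector of group labels per sample.
#' @param genes Driver gene names (non-empty).
#' @param base_rate Per-gene mutation probability in the reference groups.
#' @param enriched_odds Named numeric vector (gene -> odds multiplier > 0)
#'   applied in `enriched_group`; unlisted genes get odds 1.
#' @param enriched_group Group label receiving the odds multipliers.
#' @param mean_tmb Named numeric vector of mean non-synonymous counts per
#'   group (or a single number).
#' @param n_passenger_genes Size of the passenger gene pool.
#' @param seed Integer seed.
#' @return Mutation `data.frame` (`sample_id`, `gene`,
#'   `variant_classification`).
#' @export
simulate_mutations <- function(groups, genes, base_rate = 0.05,
                               enriched_odds = numeric(0),
                               enriched_group = NULL,
                               mean_tmb = 50, n_passenger_genes = 2000,
                               seed = 1) {
  if (length(genes) == 0) stop("driver gene list must be non-empty")
  if (any(enriched_odds <= 0)) stop("odds multipliers must be > 0")
  groups <- stats::setNames(as.character(groups), names(groups))
  glev <- unique(groups)
  if (length(mean_tmb) == 1 && is.null(names(mean_tmb)))
    mean_tmb <- stats::setNames(rep(mean_tmb, length(glev)), glev)
  if (is.null(enriched_group)) enriched_group <- glev[1L]
  odds <- stats::setNames(rep(1, length(genes)), genes)
  odds[names(enriched_odds)] <- enriched_odds
  nonsyn_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                      "Frame_Shift_Del", "Splice_Site")
  passengers <- sprintf("PSG%04d", seq_len(n_passenger_genes))
  with_seed(seed, {
    recs <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      sid <- names(groups)[i]
      g <- groups[[i]]
      n_bg <- stats::rpois(1L, mean_tmb[[g]])
      bg_genes <- if (n_bg > 0) sample(passengers, n_bg, replace = TRUE) else character(0)
      bg_class <- if (n_bg > 0)
        sample(nonsyn_classes, n_bg, replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05))
      else character(0)
      p_driver <- base_rate / (1 - base_rate)
      p <- rep(base_rate, length(genes))
      if (g == enriched_group) {
        o <- odds * p_driver
        p <- pmin(o / (1 + o), 0.99)
      }
      hit <- genes[stats::runif(length(genes)) < p]
      n_sil <- stats::rpois(1L, 0.3 * mean_tmb[[g]])
      sil_genes <- if (n_sil > 0) sample(passengers, n_sil, replace = TRUE) else character(0)
      rec_genes <- c(bg_genes, hit, sil_genes)
      recs[[i]] <- data.frame(
        sample_id = rep(sid, length(rec_genes)),
        gene = rec_genes,
        variant_classification = c(bg_class,
                                   rep("Missense_Mutation", length(hit)),
                                   rep("Silent", length(sil_genes))),
        stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, recs)
}

#' Simulate RECIST-style therapy response from a latent score
#'
#' Proportional-odds model: the cumulative log-odds of reaching at least each
#' response level (PD < SD < PR < CR) shifts linearly with the score, so a
#' higher latent immune level raises the responder rate.
#'
#' @param score Named numeric vector (roughly standardized scale).
#' @param slope Log-odds shift per unit score.
#' @param cutpoints Three increasing cutpoints on the latent logistic scale
#'   separating PD|SD|PR|CR.
#' @param seed Integer seed.
#' @return Named character vector with levels `PD`, `SD`, `PR`, `CR`.
#' @export
simulate_response <- function(score, slope = 1.5,
                              cutpoints = c(-0.2, 1.0, 2.2), seed = 1) {
  stopifnot(length(cutpoints) == 3, !is.unsorted(cutpoints))
  with_seed(seed, {
    latent <- slope * score + stats::rlogis(length(score))
  })
  lab <- cut(latent, breaks = c(-Inf, cutpoints, Inf),
             labels = c("PD", "SD", "PR", "CR"))
  stats::setNames(as.character(lab), names(score))
}

#' Simulate a complete synthetic cohort with ground truth
#'
#' Chains the component generators: a 22-type signature matrix, Dirichlet
#' mixtures in three planted immune subtypes, unstructured background genes,
#' survival whose hazard decreases with the latent cytotoxic-immune level
#' (when `log_hr < 0`), mutations with a mild excess burden in immune-low
#' samples, and proportional-odds response labels.
#'
#' @param n_samples Cohort size.
#' @param n_background_genes Unstructured log-normal noise genes appended to
#'   the mixed signature genes.
#' @param noise_sd Multiplicative noise SD for the mixtures.
#' @param log_hr Log hazard ratio per SD of latent immune level.
#' @param censor_rate Censoring probability.
#' @param seed Integer seed; every component derives its stream from it.
#' @return List of class `synthetic_cohort`: `expression` (linear),
#'   `signature`, `true_fractions`, `true_subtype`, `latent_immune` (z-scored
#'   cytotoxic fraction), `clinical`, `mutations`, `response`, `seed`.
#' @export
simulate_cohort <- function(n_samples = 300, n_background_genes = 300,
                            noise_sd = 0.2, log_hr = -1, censor_rate = 0.3,
                            seed = 1) {
  sig <- make_signature_matrix(seed = seed)
  mix <- simulate_mixtures(sig, n_samples, noise_sd = noise_sd,
                           seed = seed + 1L)
  latent <- rowSums(mix$fractions[, CYTOTOXIC_TYPES, drop = FALSE])
  latent <- as.numeric(scale(latent))
  names(latent) <- rownames(mix$fractions)

  expr <- mix$expression
  if (n_background_genes > 0) {
    with_seed(seed + 2L, {
      bg <- matrix(exp(stats::rnorm(n_background_genes * n_samples,
                                    mean = log(20), sd = 0.5)),
                   n_background_genes, n_samples)
    })
    rownames(bg) <- sprintf("BG%04d", seq_len(n_background_genes))
    colnames(bg) <- colnames(expr)
    expr <- expr_matrix(rbind(unclass(expr), bg), "linear")
  }

  clinical <- simulate_survival(latent, log_hr_per_unit = log_hr,
                                censor_rate = censor_rate, seed = seed + 3L)
  imm_group <- ifelse(latent > stats::median(latent), "immune_high", "immune_low")
  names(imm_group) <- names(latent)
  drivers <- sprintf("DRV%02d", seq_len(20))
  mut <- simulate_mutations(imm_group, drivers, base_rate = 0.08,
                            enriched_odds = stats::setNames(rep(2.5, 5), drivers[1:5]),
                            enriched_group = "immune_low",
                            mean_tmb = c(immune_high = 45, immune_low = 55),
                            seed = seed + 4L)
  resp <- simulate_response(latent, seed = seed + 5L)

  structure(list(expression = expr, signature = sig,
                 true_fractions = mix$fractions,
                 true_subtype = mix$subtype,
                 latent_immune = latent,
                 clinical = clinical, mutations = mut, response = resp,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d genes, seed %d\n",
              ncol(x$expression), nrow(x$expression), x$seed))
  cat("subtypes:", paste(names(table(x$true_subtype)),
                         table(x$true_subtype), sep = "=", collapse = " "), "\n")
  invisible(x)
}
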