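# Survival analysis surface: Kaplan-Meier curves, log-rank tests, the
# maximally selected log-rank cutoff for a continuous score, and univariate /
# stratified Cox hazard ratios. Estimators are backed by the survival
# package (Breslow tie handling for Cox); the cutoff search is implemented
# here.

#' Kaplan-Meier product-limit estimate
#'
#' Ties are handled the standard way: deaths are processed before censorings
#' at equal times. Survival starts at 1 and is non-increasing.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicator (1 = event, 0 = censored).
#' @return List of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `n_censor`.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  if (any(times < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d time points, final S(t) = %.3f\n",
              length(x$time), utils::tail(x$surv, 1L)))
  invisible(x)
}

#' Median survival time from a KM curve
#' @param km A [kaplan_meier] result.
#' @return First time at which survival drops to 0.5 or below (`NA` if never).
#' @export
km_median <- function(km) {
  idx <- which(km$surv <= 0.5)
  if (length(idx) == 0) NA_real_ else km$time[min(idx)]
}

#' Log-rank test
#'
#' Standard (O - E)^2 / V chi-square over k groups with hypergeometric
#' variance at each event time; k - 1 degrees of freedom.
#'
#' @param times,events Survival data.
#' @param groups Group label per subject (>= 2 non-empty groups).
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.character(groups)
  k <- length(unique(groups))
  if (k < 2) stop("log-rank test needs at least 2 groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- k - 1
  list(chi2 = as.numeric(fit$chisq), df = df,
       p = stats::pchisq(as.numeric(fit$chisq), df = df, lower.tail = FALSE))
}

#' Maximally selected log-rank cutoff for a continuous score
#'
#' Evaluates the standardized two-group log-rank statistic at every
#' candidate cutoff (midpoints between consecutive distinct score values)
#' for which both resulting groups hold at least `min_group_fraction` of the
#' subjects, and returns the cutoff maximizing the statistic's magnitude
#' (ties broken toward the lower cutoff). Samples with score above the
#' cutoff form the "high" group.
#'
#' @param score Finite numeric score per subject (>= 10 subjects).
#' @param times,events Survival data aligned with `score`.
#' @param min_group_fraction Minimum group size as a fraction of n.
#' @return List of class `cutoff_result`: `cutoff`, `statistic` (absolute
#'   standardized log-rank statistic at the cutoff), `candidates`
#'   (`data.frame` of cutoff and statistic), `min_group_fraction`.
#' @export
best_cutoff <- function(score, times, events, min_group_fraction = 0.1) {
  n <- length(score)
  if (n < 10) stop("need >= 10 subjects for cutoff selection")
  if (!all(is.finite(score))) stop("scores must be finite")
  s <- sort(unique(score))
  if (length(s) < 2) stop("no admissible cutoff: all scores identical")
  mids <- (utils::head(s, -1) + utils::tail(s, -1)) / 2
  min_n <- min_group_fraction * n
  stat <- rep(NA_real_, length(mids))
  for (i in seq_along(mids)) {
    hi <- score > mids[i]
    if (sum(hi) < min_n || sum(!hi) < min_n) next
    fit <- survival::survdiff(survival::Surv(times, events) ~ hi)
    stat[i] <- sqrt(as.numeric(fit$chisq))
  }
  if (all(is.na(stat))) stop("no admissible cutoff under min_group_fraction")
  best <- which(stat == max(stat, na.rm = TRUE))[1L]  # ties -> lower cutoff
  structure(list(cutoff = mids[best], statistic = stat[best],
                 candidates = data.frame(cutoff = mids, statistic = stat),
                 min_group_fraction = min_group_fraction),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff_result: cutoff = %.4g, |standardized log-rank| = %.3f\n",
              x$cutoff, x$statistic))
  invisible(x)
}

#' Univariate Cox hazard ratio for a binary group
#'
#' Partial-likelihood fit with Breslow tie handling; reports the hazard
#' ratio of `high_level` relative to the other level with a Wald 95% CI and
#' p-value. When one group has no events the likelihood is monotone: the
#' fit is flagged and the CI reported as unbounded.
#'
#' @param times,events Survival data.
#' @param group Two-level group per subject.
#' @param high_level The level whose hazard is in the numerator (defaults to
#'   the last sorted level).
#' @param stratum Label stored in the output row.
#' @return One-row `data.frame`: `stratum`, `n`, `n_event`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`, `monotone`.
#' @export
cox_hr <- function(times, events, group, high_level = NULL, stratum = "all") {
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2) stop("cox_hr expects exactly 2 groups")
  if (is.null(high_level)) high_level <- lev[2L]
  x <- as.numeric(group == high_level)
  events_by <- tapply(events, x, sum)
  monotone <- any(events_by == 0) || length(events_by) < 2
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ x, ties = "breslow"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  if (monotone) {
    ci <- c(0, Inf)
    p <- NA_real_
  } else {
    ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
    p <- 2 * stats::pnorm(-abs(beta / se))
  }
  data.frame(stratum = stratum, n = length(times),
             n_event = sum(events), hr = exp(beta),
             ci_lo = ci[1L], ci_hi = ci[2L], p = p, monotone = monotone,
             stringsAsFactors = FALSE)
}

#' Stratified hazard ratios (forest-plot table)
#'
#' Computes [cox_hr] of the high vs low score group within every stratum of
#' each clinical covariate. Strata below `min_n` subjects, with a single
#' score group, or with no events are skipped with a message.
#'
#' @param clinical Clinical `data.frame` with `sample_id`, `os_time`,
#'   `os_event` and covariate columns.
#' @param groups Named vector of "high"/"low" per sample.
#' @param strata_definitions Named list: covariate column -> either `NULL`
#'   (use each observed level) or a numeric vector of cut breaks for a
#'   continuous covariate.
#' @param min_n Minimum stratum size.
#' @return `data.frame` of per-stratum hazard ratios (high vs low).
#' @export
stratified_forest <- function(clinical, groups, strata_definitions,
                              min_n = 10) {
  g <- groups[clinical$sample_id]
  out <- list()
  for (cov in names(strata_definitions)) {
    if (!cov %in% names(clinical)) {
      message("covariate not in clinical table, skipped: ", cov)
      next
    }
    val <- clinical[[cov]]
    breaks <- strata_definitions[[cov]]
    lev <- if (is.null(breaks)) as.character(val)
           else as.character(cut(val, breaks = breaks))
    for (lv in stats::na.omit(unique(lev))) {
      idx <- which(lev == lv)
      nm <- paste0(cov, "=", lv)
      if (length(idx) < min_n || length(unique(g[idx])) < 2 ||
          sum(clinical$os_event[idx]) == 0) {
        message("stratum skipped (too small or degenerate): ", nm)
        next
      }
      out[[nm]] <- cox_hr(clinical$os_time[idx], clinical$os_event[idx],
                          g[idx], high_level = "high", stratum = nm)
    }
  }
  if (length(out) == 0)
    return(data.frame(stratum = character(0), n = integer(0),
                      n_event = numeric(0), hr = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0), p = numeric(0),
                      monotone = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
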