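# Therapy-response evaluation: ROC/AUC of the score against a binary
# outcome, and response-rate contrasts between score groups.

#' ROC curve and AUC for a score against a binary outcome
#'
#' AUC uses the rank (Mann-Whitney) formulation with midranks, so ties are
#' handled exactly; the full curve (sensitivity/specificity at every
#' distinct threshold) is returned for plotting. Higher scores are assumed
#' to predict the positive class.
#'
#' @param scores Numeric score per subject.
#' @param outcome Binary outcome (logical, 0/1, or two-level factor where
#'   the second sorted level is positive).
#' @return List of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_auc <- function(scores, outcome) {
  y <- if (is.logical(outcome)) outcome
       else if (is.numeric(outcome)) outcome == 1
       else as.character(outcome) == sort(unique(as.character(outcome)))[2L]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & y) / n1, 0)
  spec <- vapply(thr, function(t) sum(scores < t & !y) / n0, 0)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f over %d thresholds\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Response-rate table by score group
#'
#' Per-group proportions of each RECIST-style response category and a 2 x k
#' chi-square test for association (no continuity correction for df > 1).
#'
#' @param response Named response label per sample (e.g. CR/PR/SD/PD).
#' @param groups Named "high"/"low" group per sample.
#' @param levels Category order for the output columns.
#' @return List: `proportions` (group x category matrix, rows sum to 1),
#'   `counts`, `chi2`, `df`, `p`.
#' @export
response_rate_table <- function(response, groups,
                                levels = c("CR", "PR", "SD", "PD")) {
  ids <- intersect(names(response), names(groups))
  if (length(unique(groups[ids])) < 2) stop("both score groups must be non-empty")
  tab <- table(factor(groups[ids]), factor(response[ids], levels = levels))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  props <- sweep(tab, 1L, rowSums(tab), "/")
  list(proportions = props, counts = tab,
       chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Collapse RECIST categories to responder / non-responder
#'
#' CR and PR count as responders (the conventional dichotomization).
#' @param response Character vector of CR/PR/SD/PD labels.
#' @return Logical vector (`TRUE` = responder), names preserved.
#' @export
as_responder <- function(response) {
  stats::setNames(response %in% c("CR", "PR"), names(response))
}
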