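# Independent oracles used across the suite. Each is a deliberately naive,
# brute-force implementation that shares no code with the package.

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Product-limit estimator computed literally from risk sets.
km_brute <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Two-group log-rank z statistic from first principles (O - E over V, group 1
# = `in_group`).
logrank_z_brute <- function(times, events, in_group) {
  ut <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & in_group)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & in_group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E) / sqrt(V)
}

# Breslow partial log-likelihood for a single binary covariate.
breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Literal BH step-up: sort, scale by n/i, cummin from the largest.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# AUC by brute-force pair counting (ties count 1/2).
auc_pairs_brute <- function(scores, y) {
  pos <- scores[y]
  neg <- scores[!y]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Nonnegative least-squares fractions on the same z-scored system the
# deconvolution uses, via an independent solver.
nnls_fractions <- function(bulk_col, sig) {
  Xz <- scale(unclass(sig))
  yz <- as.numeric(scale(bulk_col))
  w <- pracma::lsqnonneg(Xz, yz)$x
  if (sum(w) > 0) w / sum(w) else w
}

# Shared tiny fixtures ------------------------------------------------------

make_tiny_expr <- function(values, scale = "log2") {
  expr_matrix(values, scale)
}

# Three well-separated Gaussian blobs in 2-D (the planted-partition fixture).
make_blobs <- function(n_per = 20, sd = 0.1, seed = 42) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))))
  rownames(x) <- paste0("it", seq_len(3 * n_per))
  list(data = x, truth = rep(1:3, each = n_per))
}
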