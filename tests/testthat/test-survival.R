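test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-15)

  cens <- kaplan_meier(c(2, 4, 7), c(0, 0, 0))
  expect_true(all(cens$surv == 1))

  set.seed(3)
  times <- round(rexp(20, 0.1), 1)
  events <- rbinom(20, 1, 0.7)
  km20 <- kaplan_meier(times, events)
  oracle <- km_brute(times, events)
  at_events <- km20$surv[match(oracle$time, km20$time)]
  expect_equal(at_events, oracle$surv, tolerance = 1e-12)

  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("log-rank test is null on duplicated data and powered under HR 3", {
  t0 <- c(1, 3, 5, 7, 9)
  e0 <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 5))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  lr3 <- logrank_test(c(t0, t0, t0), c(e0, e0, e0),
                      rep(c("a", "b", "c"), each = 5))
  expect_equal(lr3$chi2, 0, tolerance = 1e-12)
  expect_identical(lr3$df, 2)

  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    times <- c(rexp(200, 0.1), rexp(200, 0.3))
    p <- logrank_test(times, rep(1, 400), rep(c("lo", "hi"), each = 200))$p
    if (p < 1e-4) hits <- hits + 1
  }
  expect_gte(hits, 19)

  expect_error(logrank_test(t0, e0, rep("a", 5)), "2 groups")
})

test_that("log-rank is invariant to common monotone time transforms", {
  set.seed(5)
  times <- rexp(80, 0.2)
  events <- rbinom(80, 1, 0.8)
  g <- rep(c("a", "b"), 40)
  a <- logrank_test(times, events, g)
  b <- logrank_test(log1p(times) * 100, events, g)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
})

test_that("best cutoff matches exhaustive search against a first-principles statistic", {
  set.seed(11)
  n <- 30
  score <- rnorm(n)
  times <- rexp(n, 0.1 * ifelse(score > 0.3, 3, 1))
  events <- rbinom(n, 1, 0.8)
  res <- best_cutoff(score, times, events, min_group_fraction = 0.1)

  s <- sort(unique(score))
  mids <- (head(s, -1) + tail(s, -1)) / 2
  admissible <- vapply(mids, function(ct)
    min(sum(score > ct), sum(score <= ct)) >= 0.1 * n, TRUE)
  z <- vapply(mids, function(ct)
    abs(logrank_z_brute(times, events, score > ct)), 0)
  z[!admissible] <- NA
  expect_equal(res$cutoff, mids[which.max(z)])
  expect_equal(res$statistic, max(z, na.rm = TRUE), tolerance = 1e-8)

  expect_error(best_cutoff(rep(1, 20), rexp(20), rbinom(20, 1, 0.5)),
               "identical")
})

test_that("planted hazard change-point is localized by the cutoff search", {
  inside <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 400
    score <- runif(n, -1, 1)
    times <- rexp(n, 0.05 * ifelse(score > 0, 2, 1))
    res <- best_cutoff(score, times, rep(1, n))
    band <- quantile(score, c(0.4, 0.6))
    if (res$cutoff >= band[1] && res$cutoff <= band[2]) inside <- inside + 1
  }
  expect_gte(inside, 8)
})

test_that("Cox hazard ratios match the partial-likelihood optimum", {
  t0 <- c(1, 3, 5, 7, 9)
  e0 <- c(1, 0, 1, 1, 0)
  same <- cox_hr(c(t0, t0), c(e0, e0), rep(c("low", "high"), each = 5),
                 high_level = "high")
  expect_equal(same$hr, 1, tolerance = 1e-6)

  set.seed(7)
  score <- rep(c(0, 1), each = 1000)
  times <- rexp(2000, 0.1 * exp(-score))
  hr <- cox_hr(times, rep(1, 2000), ifelse(score == 1, "high", "low"),
               high_level = "high")
  expect_lt(abs(log(hr$hr) - (-1)), 0.15)
  expect_true(hr$ci_lo < hr$hr && hr$hr < hr$ci_hi)

  # 10-subject fixture vs numeric maximum of the Breslow partial likelihood
  x <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  t10 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  e10 <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  fit <- cox_hr(t10, e10, ifelse(x == 1, "high", "low"), high_level = "high")
  opt <- optimize(function(b) breslow_loglik(b, t10, e10, x),
                  interval = c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(log(fit$hr), opt$maximum, tolerance = 1e-4)

  # no events in one group: monotone likelihood flagged, CI unbounded
  mono <- cox_hr(c(1, 2, 3, 4), c(1, 1, 0, 0), c("low", "low", "high", "high"),
                 high_level = "high")
  expect_true(mono$monotone)
  expect_equal(mono$ci_hi, Inf)
})

test_that("KM ordering and Cox direction agree on non-crossing fixtures", {
  set.seed(9)
  times <- c(rexp(150, 0.3), rexp(150, 0.1))
  events <- rep(1, 300)
  g <- rep(c("high", "low"), each = 150)  # "high" has the higher hazard here
  hr <- cox_hr(times, events, g, high_level = "high")
  expect_gt(hr$hr, 1)
  km_h <- kaplan_meier(times[1:150], events[1:150])
  km_l <- kaplan_meier(times[151:300], events[151:300])
  expect_lt(km_median(km_h), km_median(km_l))
})

test_that("stratified forest reduces to the unstratified fit and skips degenerate strata", {
  set.seed(10)
  n <- 120
  clinical <- data.frame(sample_id = paste0("s", 1:n),
                         os_time = rexp(n, 0.1),
                         os_event = rbinom(n, 1, 0.8),
                         sex = rep(c("F", "M"), n / 2),
                         rare = c(rep("big", n - 3), rep("tiny", 3)),
                         whole = "all",
                         stringsAsFactors = FALSE)
  groups <- setNames(rep(c("high", "low"), each = n / 2), clinical$sample_id)
  suppressMessages({
    fr <- stratified_forest(clinical, groups,
                            list(whole = NULL, sex = NULL, rare = NULL))
  })
  expect_false("rare=tiny" %in% fr$stratum)
  expect_true(all(c("sex=F", "sex=M", "whole=all") %in% fr$stratum))
  direct <- cox_hr(clinical$os_time, clinical$os_event, groups,
                   high_level = "high")
  expect_equal(fr$hr[fr$stratum == "whole=all"], direct$hr, tolerance = 1e-12)
  expect_equal(fr$p[fr$stratum == "whole=all"], direct$p, tolerance = 1e-12)
})
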