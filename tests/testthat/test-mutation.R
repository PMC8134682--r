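table1_path <- function() {
  system.file("extdata", "table1_mutation_contrasts.tsv", package = "iciscope",
              mustWork = FALSE)
}

read_table1 <- function() {
  p <- table1_path()
  if (!nzchar(p) || !file.exists(p))
    p <- file.path("..", "..", "inst", "extdata",
                   "table1_mutation_contrasts.tsv")
  read.delim(p, stringsAsFactors = FALSE)
}

test_that("TMB counts only non-synonymous records and fills absent samples", {
  mut <- data.frame(
    sample_id = c(rep("s1", 5), "s2"),
    gene = c("A", "B", "C", "D", "E", "A"),
    variant_classification = c("Missense_Mutation", "Missense_Mutation",
                               "Missense_Mutation", "Silent", "Silent",
                               "Nonsense_Mutation"),
    stringsAsFactors = FALSE)
  suppressMessages(tmb <- compute_tmb(mut, c("s1", "s2", "s3")))
  expect_equal(tmb$nonsyn_count[tmb$sample_id == "s1"], 3L)
  expect_equal(tmb$nonsyn_count[tmb$sample_id == "s2"], 1L)
  expect_equal(tmb$nonsyn_count[tmb$sample_id == "s3"], 0L)
  expect_identical(tmb$tmb_group, c("high", "low", "low"))  # median split = 1

  empty <- mut[0, ]
  suppressMessages(t0 <- compute_tmb(empty, c("s1", "s2")))
  expect_true(all(t0$nonsyn_count == 0))

  set.seed(2)
  n <- 400
  g <- setNames(rep("x", n), paste0("s", 1:n))
  sim <- simulate_mutations(g, "G1", base_rate = 0, mean_tmb = 50, seed = 5)
  suppressMessages(ts <- compute_tmb(sim, names(g)))
  expect_lt(abs(mean(ts$nonsyn_count) - 50), 3 * sqrt(50 / n))
})

test_that("Yates-corrected chi-square reproduces the published contrasts", {
  glrb <- contingency_chisq(192, 5, 221, 29)
  expect_equal(signif(glrb$p, 3), signif(0.000653446, 3))
  lrp1b <- contingency_chisq(143, 54, 154, 96)
  expect_equal(signif(lrp1b$p, 3), signif(0.019185781, 3))

  # identical mutation proportions: corrected statistic sits at the boundary
  flat <- contingency_chisq(100, 10, 200, 20)
  expect_gte(flat$p, 0.9)

  degen <- contingency_chisq(100, 0, 200, 0)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p))
})

test_that("the full published contrast table reproduces row by row", {
  tab <- read_table1()
  expect_gte(nrow(tab), 50)
  expect_true(all(tab$high_wild + tab$high_mut == 197))
  expect_true(all(tab$low_wild + tab$low_mut == 250))
  for (i in seq_len(nrow(tab))) {
    ct <- contingency_chisq(tab$high_wild[i], tab$high_mut[i],
                            tab$low_wild[i], tab$low_mut[i])
    expect_equal(signif(ct$p, 3), signif(tab$p_printed[i], 3),
                 info = tab$gene[i])
  }
  # printed percentages recompute from the margins to 2 decimals
  expect_equal(round(100 * tab$high_mut / 197, 2), tab$high_mut_pct)
  expect_equal(round(100 * tab$high_wild / 197, 2), tab$high_wild_pct)
  expect_equal(round(100 * tab$low_mut / 250, 2), tab$low_mut_pct)
  expect_equal(round(100 * tab$low_wild / 250, 2), tab$low_wild_pct)
})

test_that("per-gene contrasts build the 2x2 table from MAF records", {
  groups <- setNames(rep(c("high", "low"), c(4, 4)), paste0("s", 1:8))
  mut <- data.frame(
    sample_id = c("s1", "s5", "s6", "s7", "s8"),
    gene = "G1",
    variant_classification = c("Missense_Mutation", "Missense_Mutation",
                               "Nonsense_Mutation", "Missense_Mutation",
                               "Silent"),
    stringsAsFactors = FALSE)
  row <- gene_group_chisq(mut, groups, "G1")
  expect_equal(row[, c("high_wild", "high_mut", "low_wild", "low_mut")],
               data.frame(high_wild = 3L, high_mut = 1L, low_wild = 1L,
                          low_mut = 3L))
  oracle <- suppressWarnings(
    chisq.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)))
  expect_equal(row$p, oracle$p.value)
})

test_that("frequency table ranks genes with alphabetical tie-breaks and multi-hit collapse", {
  groups <- setNames(rep(c("high", "low"), each = 2), paste0("s", 1:4))
  mut <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s1", "s2", "s1", "s1"),
    gene = c("EVERY", "EVERY", "EVERY", "EVERY", "ZETA", "ALPHA", "ALPHA",
             "ALPHA"),
    variant_classification = "Missense_Mutation",
    stringsAsFactors = FALSE)
  res <- mutation_frequency_table(mut, groups)
  expect_identical(res$frequencies$gene[1], "EVERY")
  expect_equal(res$frequencies$freq[1], 1.0)
  # ALPHA and ZETA both mutate 25-50%: equal-frequency ties are alphabetical
  both <- res$frequencies[res$frequencies$gene %in% c("ALPHA", "ZETA"), ]
  if (both$freq[1] == both$freq[2])
    expect_identical(both$gene, sort(both$gene))
  expect_identical(res$oncoprint["s1", "ALPHA"], "Multi_Hit")
  expect_identical(res$oncoprint["s1", "ZETA"], "Missense_Mutation")
  expect_identical(res$oncoprint["s3", "ZETA"], "")
  # published-style frequency recomputation: count / group margin
  expect_equal(round(100 * 5 / 197, 2), 2.54)
})

test_that("score-TMB correlation behaves at the extremes and under the null", {
  s <- setNames(c(3, 2, 1), c("a", "b", "c"))
  t_up <- setNames(c(1, 2, 3), c("a", "b", "c"))
  expect_equal(score_tmb_correlation(s, t_up)$rho, -1)
  expect_equal(score_tmb_correlation(t_up, t_up)$rho, 1)
  expect_error(score_tmb_correlation(setNames(rep(1, 3), names(s)), t_up),
               "constant")

  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    a <- setNames(rnorm(500), paste0("s", 1:500))
    b <- setNames(rpois(500, 30), paste0("s", 1:500))
    if (abs(score_tmb_correlation(a, b)$rho) < 0.12) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("bivariate TMB x score survival stratification", {
  t0 <- c(2, 4, 6, 8, 10)
  e0 <- c(1, 1, 0, 1, 0)
  ids <- paste0("s", 1:20)
  clinical <- data.frame(sample_id = ids, os_time = rep(t0, 4),
                         os_event = rep(e0, 4), stringsAsFactors = FALSE)
  tmbg <- setNames(rep(c("high", "low"), each = 10), ids)
  icig <- setNames(rep(rep(c("high", "low"), each = 5), 2), ids)
  res <- bivariate_survival(tmbg, icig, clinical)
  expect_length(res$km, 4L)
  expect_equal(res$logrank$chi2, 0, tolerance = 1e-12)

  # score effect within each TMB level shows up in the medians
  ok <- 0
  for (seed in 1:5) {
    ch <- simulate_cohort(n_samples = 200, n_background_genes = 10,
                          seed = seed, censor_rate = 0.1)
    lat <- ch$latent_immune
    icig2 <- setNames(ifelse(lat > median(lat), "high", "low"), names(lat))
    suppressMessages(tmb <- compute_tmb(ch$mutations, names(lat)))
    tmbg2 <- setNames(tmb$tmb_group, tmb$sample_id)
    res2 <- bivariate_survival(tmbg2, icig2, ch$clinical)
    med <- vapply(res2$km, km_median, 0)
    if (med[["TMB_high/ICI_high"]] > med[["TMB_high/ICI_low"]] &&
        med[["TMB_low/ICI_high"]] > med[["TMB_low/ICI_low"]]) ok <- ok + 1
  }
  expect_gte(ok, 4)

  one <- clinical[1:5, ]
  all_high <- setNames(rep("high", 5), one$sample_id)
  expect_warning(expect_error(bivariate_survival(all_high, all_high, one),
                              "2 groups"),
                 "dropped")
})
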