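test_that("signature partition follows the sign of the cluster association", {
  labels <- rep(c("C", "B", "A"), each = 10)   # ordered worst -> best
  n <- length(labels)
  up <- rep(c(1, 2, 3), each = 10)             # rises along cluster order
  down <- rev(up)
  flat <- rep(5, n)
  set.seed(2)
  x <- rbind(up = up + rnorm(n, 0, 0.01),
             down = down + rnorm(n, 0, 0.01),
             flat = flat)
  colnames(x) <- paste0("s", 1:n)
  m <- expr_matrix(x, "log2")
  part <- assign_signatures(m, labels, cluster_order = c("C", "B", "A"))
  expect_identical(part$genes_A, "up")
  expect_identical(part$genes_B, "down")
  expect_identical(part$stats$signature[part$stats$gene == "flat"], "excluded")

  expect_error(assign_signatures(m, labels[-1]), "every sample")
  expect_error(assign_signatures(m, labels, cluster_order = c("X", "Y", "Z")),
               "observed clusters")
})

test_that("planted immune-activation genes land in signature A", {
  ch <- simulate_cohort(n_samples = 120, n_background_genes = 50, seed = 3)
  log_expr <- to_log2(ch$expression)
  # truth-driven gene clusters: tertiles of the latent immune level
  tert <- cut(ch$latent_immune, quantile(ch$latent_immune, c(0, 1/3, 2/3, 1)),
              labels = c("C", "B", "A"), include.lowest = TRUE)
  cyto_markers <- rownames(ch$signature)[
    sub("\\.M\\d+$", "", rownames(ch$signature)) %in%
      c("CD8_T", "NK_activated", "CD4_T_memory_activated", "T_follicular_helper")]
  part <- assign_signatures(log_expr[cyto_markers, ], as.character(tert),
                            cluster_order = c("C", "B", "A"))
  expect_gte(length(part$genes_A) / length(cyto_markers), 0.9)
})

test_that("shadow-feature selection separates informative from noise features", {
  set.seed(6)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  info <- matrix(rnorm(n * 5, mean = rep(c(0, 1.5), each = n / 2)), n, 5)
  for (seed in 1:3) {
    set.seed(seed + 100)
    noise <- matrix(rnorm(n * 50), n, 50)
    x <- cbind(info, noise)
    colnames(x) <- c(paste0("inf", 1:5), paste0("noise", 1:50))
    res <- boruta_select(x, y, n_iter = 25, seed = seed)
    expect_length(intersect(paste0("inf", 1:5), res$confirmed), 5L)
    expect_lte(length(intersect(paste0("noise", 1:50), res$confirmed)), 2L)
  }
})

test_that("shadow selection edge cases behave as the binomial decision implies", {
  set.seed(9)
  n <- 60
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- cbind(label_copy = as.numeric(y == "a"),
             matrix(rnorm(n * 10), n, 10))
  colnames(x)[-1] <- paste0("n", 1:10)
  res <- boruta_select(x, y, n_iter = 25, seed = 4)
  expect_true("label_copy" %in% res$confirmed)

  one <- boruta_select(x, y, n_iter = 1, seed = 4)
  expect_length(one$confirmed, 0L)   # a single iteration cannot reject chance
  expect_length(one$rejected, 0L)

  expect_error(boruta_select(x, factor(rep("a", n)), n_iter = 5), "2 classes")
  expect_error(boruta_select(x[1:10, ], y[1:10], n_iter = 5), ">= 20")
})

test_that("PC1 score tracks the dominant expression axis with a fixed sign", {
  set.seed(12)
  profile <- rnorm(40)
  x <- rbind(g1 = 2 + 3 * profile, g2 = -1 + 0.5 * profile)
  colnames(x) <- paste0("s", 1:40)
  s <- pc1_score(expr_matrix(x, "log2"))
  expect_equal(abs(cor(s, profile)), 1, tolerance = 1e-12)
  expect_gt(cor(s, colMeans(t(scale(t(x))))), 0)

  # rank-1 + small noise: PC1 dominates the spectrum
  set.seed(13)
  load <- runif(30, 0.5, 1.5)
  big <- outer(load, profile) + matrix(rnorm(30 * 40, 0, 0.05), 30)
  dimnames(big) <- list(paste0("g", 1:30), paste0("s", 1:40))
  s2 <- pc1_score(expr_matrix(big, "log2"))
  expect_gte(attr(s2, "var_explained"), 0.9)

  withz <- rbind(big, zv = rep(1, 40))
  expect_warning(pc1_score(expr_matrix(withz, "log2")), "zero-variance")
})

test_that("ICI score is the signed difference of the two block scores", {
  set.seed(14)
  x <- matrix(rnorm(30 * 25), 30, 25,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:25)))
  m <- expr_matrix(x, "log2")
  part <- list(genes_A = paste0("g", 1:10), genes_B = paste0("g", 11:20))
  tab <- compute_ici_score(m, part)
  expect_equal(tab$ici_score, tab$pc1a - tab$pc1b, tolerance = 1e-12)

  # swapping A and B negates the score exactly
  swapped <- compute_ici_score(m, list(genes_A = part$genes_B,
                                       genes_B = part$genes_A))
  expect_equal(swapped$ici_score, -tab$ici_score, tolerance = 1e-12)

  # a missing B block leaves the score equal to PC1A
  only_a <- compute_ici_score(m, list(genes_A = part$genes_A,
                                      genes_B = character(0)))
  expect_equal(only_a$ici_score, only_a$pc1a)
  expect_true(all(only_a$pc1b == 0))

  expect_error(compute_ici_score(m, list(genes_A = "zz", genes_B = "yy")),
               "no signature genes")
})

test_that("ICI score is invariant under per-gene affine transforms", {
  set.seed(15)
  x <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:30)))
  part <- list(genes_A = paste0("g", 1:8), genes_B = paste0("g", 13:20))
  a <- compute_ici_score(expr_matrix(x, "log2"), part)
  scale_g <- runif(20, 0.5, 4)
  shift_g <- rnorm(20, 0, 10)
  y <- x * scale_g + shift_g
  b <- compute_ici_score(expr_matrix(y, "log2"), part)
  expect_equal(a$ici_score, b$ici_score, tolerance = 1e-8)
})

test_that("adding one noise gene barely perturbs the score ranking", {
  set.seed(16)
  profile <- rnorm(50)
  blockA <- outer(runif(10, 0.8, 1.2), profile) +
    matrix(rnorm(500, 0, 0.1), 10)
  blockB <- matrix(rnorm(8 * 50), 8, 50)
  x <- rbind(blockA, blockB, noise = rnorm(50))
  dimnames(x) <- list(c(paste0("a", 1:10), paste0("b", 1:8), "noise"),
                      paste0("s", 1:50))
  m <- expr_matrix(x, "log2")
  base <- compute_ici_score(m, list(genes_A = paste0("a", 1:10),
                                    genes_B = paste0("b", 1:8)))
  plus <- compute_ici_score(m, list(genes_A = c(paste0("a", 1:10), "noise"),
                                    genes_B = paste0("b", 1:8)))
  expect_gte(cor(base$ici_score, plus$ici_score, method = "spearman"), 0.99)
})

test_that("score groups split consistently at the cutoff", {
  tab <- data.frame(sample_id = paste0("s", 1:6), pc1a = 1:6, pc1b = 0,
                    ici_score = c(-2, -1, 0, 1, 2, 3))
  g <- assign_score_groups(tab, 0.5)
  expect_identical(g$group, c("low", "low", "low", "high", "high", "high"))
  expect_true(all(g$cutoff_used == 0.5))
})
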