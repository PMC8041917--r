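# Sign-weighted Fisher statistic, empirical null, per-gene empirical
# p-values and gene-set aggregation.

test_that("weighted Fisher statistic matches hand-computed values", {
  # ln(1) = 0 regardless of signs
  expect_equal(weighted_fisher_statistic(c(1, 1, 1), c(1, -1, 2)), 0)
  # |ln 0.01 + ln 0.04 - ln 0.5|
  expect_equal(weighted_fisher_statistic(c(0.01, 0.04, 0.5),
                                         c(1.2, 0.3, -0.2)),
               abs(log(0.01) + log(0.04) - log(0.5)),
               tolerance = 1e-12)
  # 11 tissues at p = 0.01, all same direction: 11 * |ln 0.01|
  expect_equal(weighted_fisher_statistic(rep(0.01, 11), rep(2, 11)),
               11 * abs(log(0.01)), tolerance = 1e-12)
})

test_that("statistic is invariant under a global sign flip and zero logFC drops out", {
  p <- c(0.2, 0.05, 0.6, 0.01)
  lfc <- c(1.5, -0.2, 0.7, -2)
  expect_equal(weighted_fisher_statistic(p, lfc),
               weighted_fisher_statistic(p, -lfc))
  # sgn(0) = 0: the cell contributes nothing
  expect_equal(weighted_fisher_statistic(c(0.001, 0.5), c(0, 1)),
               weighted_fisher_statistic(0.5, 1))
})

test_that("statistic rejects invalid domains", {
  expect_error(weighted_fisher_statistic(c(0, 0.5), c(1, 1)), "0, 1")
  expect_error(weighted_fisher_statistic(c(0.5, 1.2), c(1, 1)), "0, 1")
  expect_error(weighted_fisher_statistic(c(0.5, 0.5), 1), "length")
  expect_error(weighted_fisher_statistic(numeric(0), numeric(0)), "at least one")
  expect_error(weighted_fisher_statistic(c(NA, 0.5), c(1, 1)), "missing")
})

test_that("statistic matches an independent brute-force oracle on random inputs", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(1:5, 1)
    p <- runif(n, min = 1e-6, max = 1)
    lfc <- rnorm(n)
    if (i %% 7 == 0) lfc[1] <- 0
    expect_equal(weighted_fisher_statistic(p, lfc),
                 brute_force_signed_logsum(p, lfc),
                 tolerance = 1e-12)
  }
})

test_that("with agreeing signs the statistic decreases in each p", {
  p <- c(0.3, 0.1, 0.2)
  lfc <- c(1, 2, 0.5)
  base <- weighted_fisher_statistic(p, lfc)
  for (j in seq_along(p)) {
    p2 <- p
    p2[j] <- p[j] * 0.5
    expect_gt(weighted_fisher_statistic(p2, lfc), base)
  }
})

test_that("empirical null is deterministic, sorted, and degenerate when all p = 1", {
  p <- matrix(1, 5, 3)
  lfc <- matrix(rnorm(15), 5, 3)
  m <- cross_tissue_matrix(p, lfc)
  null <- build_empirical_null(m, n_rounds = 50, seed = 9)
  expect_length(null$samples, 50)
  expect_true(all(null$samples == 0))

  sim <- simulate_cross_tissue_table(cross_tissue_sim_config(
    n_genes = 40, n_tissues = 4, seed = 5))
  n1 <- build_empirical_null(sim$matrix, n_rounds = 4, seed = 11)
  n2 <- build_empirical_null(sim$matrix, n_rounds = 4, seed = 11)
  expect_identical(n1$samples, n2$samples)
  expect_length(n1$samples, 4)
  expect_false(is.unsorted(n1$samples))
  n3 <- build_empirical_null(sim$matrix, n_rounds = 4, seed = 12)
  expect_false(identical(n1$samples, n3$samples))
})

test_that("pure-null resampled null matches the signed-exponential-sum oracle", {
  # under the null, -ln p ~ Exp(1) and signs are +/-1 equiprobable, so F is
  # |sum of l signed Exp(1)|; compare medians with a direct Monte-Carlo oracle
  sim <- simulate_cross_tissue_table(cross_tissue_sim_config(
    n_genes = 3000, n_tissues = 11, seed = 21))
  null <- build_empirical_null(sim$matrix, n_rounds = 20000, seed = 22)
  set.seed(23)
  oracle <- replicate(20000, abs(sum(rexp(11) * sample(c(-1, 1), 11, TRUE))))
  expect_equal(median(null$samples), median(oracle), tolerance = 0.05)
  expect_equal(quantile(null$samples, 0.9), quantile(oracle, 0.9),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("per-tissue resampling scheme also yields a calibrated null", {
  sim <- simulate_cross_tissue_table(cross_tissue_sim_config(
    n_genes = 1500, n_tissues = 6, seed = 31))
  res <- run_cross_tissue_analysis(sim$matrix, n_rounds = 4000, seed = 32,
                                   scheme = "per_tissue", alpha = 0.05)
  rate <- mean(res$genes$significant)
  se <- sqrt(0.05 * 0.95 / nrow(res$genes))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("empirical p-value follows the plus-one tail-count rule", {
  null <- build_empirical_null(
    cross_tissue_matrix(matrix(0.5, 2, 2), matrix(1, 2, 2)),
    n_rounds = 4, seed = 1)
  null$samples <- c(1, 2, 3, 4)  # fixed samples for the arithmetic check
  expect_equal(empirical_pvalue(2.5, null), (1 + 2) / (1 + 4))
  expect_equal(empirical_pvalue(0, null), 1)
  expect_equal(empirical_pvalue(99, null), 1 / 5)
  expect_equal(empirical_pvalue(2, null), (1 + 3) / (1 + 4))  # ties in tail
  # monotone non-increasing in F, bounded below by 1/(n+1)
  f <- seq(0, 5, by = 0.25)
  rho <- empirical_pvalue(f, null)
  expect_true(all(diff(rho) <= 0))
  expect_true(all(rho >= 1 / 5 & rho <= 1))
  expect_error(empirical_pvalue(-1, null), "non-negative")
})

test_that("gene-set Fisher aggregation matches the chi-square closed form", {
  r <- aggregate_geneset(c(1, 1, 1))
  expect_equal(r$script_F, 0)
  expect_equal(r$p_geneset, 1)

  r2 <- aggregate_geneset(c(0.5, 0.5))
  expect_equal(r2$script_F, 2 * log(0.5), tolerance = 1e-12)
  expect_equal(r2$p_geneset, pchisq(-4 * log(0.5), df = 4, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(aggregate_geneset(c(0.5, 0)), "0, 1")
  expect_error(aggregate_geneset(numeric(0)), "non-empty")
})

test_that("Fisher aggregation of a single p-value is the identity", {
  for (rho in c(0.01, 0.2, 0.77, 1)) {
    expect_equal(aggregate_geneset(rho)$p_geneset, rho, tolerance = 1e-12)
  }
})

test_that("full analysis recovers planted signal genes and validates the geneset", {
  cfg <- cross_tissue_sim_config(n_genes = 600, n_tissues = 11,
                                 n_signal_genes = 2,
                                 signal_p_law = list(type = "fixed", value = 1e-3),
                                 signal_sign = 1L, seed = 41)
  sim <- simulate_cross_tissue_table(cfg)
  planted <- sim$truth$gene_id[sim$truth$is_signal]
  geneset <- c(planted, sim$truth$gene_id[3:7])
  res <- run_cross_tissue_analysis(sim$matrix, geneset = geneset,
                                   alpha = 0.01, n_rounds = 3000, seed = 42)
  flagged <- res$genes$gene_id[res$genes$significant]
  expect_true(all(planted %in% flagged))
  expect_lt(res$geneset$p_geneset, 0.01)
  expect_error(
    run_cross_tissue_analysis(sim$matrix, geneset = c(planted, "nope"),
                              n_rounds = 10, seed = 1),
    "nope")
})

test_that("missing tissues are dropped per gene and counted", {
  p <- matrix(runif(12, 0.01, 1), 4, 3)
  lfc <- matrix(rnorm(12), 4, 3)
  p[1, 2] <- NA; lfc[1, 2] <- NA
  m <- cross_tissue_matrix(p, lfc)
  res <- run_cross_tissue_analysis(m, n_rounds = 100, seed = 2)
  expect_equal(res$genes$n_tissues_used, c(2L, 3L, 3L, 3L))
  expect_equal(res$genes$F[1],
               weighted_fisher_statistic(p[1, -2], lfc[1, -2]))
  # per-gene nulls rank short genes against same-width pseudo-genes
  res2 <- run_cross_tissue_analysis(m, n_rounds = 100, seed = 2,
                                    per_gene_null = TRUE)
  expect_true(all(res2$genes$rho >= 1 / 101 & res2$genes$rho <= 1))
})
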