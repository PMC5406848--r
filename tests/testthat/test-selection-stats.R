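test_that("enrichment statistics and binomial p behave as specified", {
  L1 <- 1e6; L2 <- 1e6
  even <- enrichment_test(10, 10, L1, L2)
  expect_equal(even$odds_ratio, 1.00)
  expect_equal(even$rate_ratio, 1.00)
  # symmetric counts under p0 = 0.5 give p = 1
  expect_equal(even$p_binomial_two_tailed, 1)

  # undefined odds ratio is flagged, p still computed
  zero_flex <- enrichment_test(5, 0, L1, L2)
  expect_true(is.na(zero_flex$odds_ratio))
  expect_true(zero_flex$p_binomial_two_tailed > 0)
})

test_that("binomial two-tailed p equals the enumeration oracle for n <= 12", {
  for (n in c(3, 7, 12)) {
    for (p0 in c(0.3, 0.4848745, 0.7)) {
      for (k in 0:n) {
        got <- enrichment_test(k, n - k, p0 * 1e6, (1 - p0) * 1e6)
        expect_equal(got$p_binomial_two_tailed,
                     oracle_binom_two_tailed(k, n, got$p0),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("dN/dS is a normalized count ratio", {
  expect_equal(dnds_ratio(0, 5, 3.22)$dnds, 0)
  expect_error(dnds_ratio(10, 0, 3.22), "syn_n must be positive")
  # scaling invariance
  base <- dnds_ratio(51, 10, 3.22)$dnds
  expect_equal(dnds_ratio(51 * 7, 10 * 7, 3.22)$dnds, base)
})

test_that("G scores follow the likelihood-score definition", {
  tab <- gscores(tibble::tibble(gene_id = c("a", "b", "c"),
                                L = c(300, 300, 400),
                                O = c(4, 0, 1)))
  expect_equal(sum(tab$E), sum(tab$O), tolerance = 1e-9)
  expect_equal(tab$G[tab$gene_id == "b"], 0)  # O = 0 convention
  # O = E gives G = 0 exactly
  flat <- gscores(tibble::tibble(gene_id = c("a", "b"), L = c(100, 100),
                                 O = c(3, 3)))
  expect_equal(flat$G, c(0, 0))
  # direct numeric case: O = 4, E = 1
  one <- gscores(tibble::tibble(gene_id = c("a", "b"), L = c(100, 300),
                                O = c(4, 0)))
  expect_equal(one$E[1], 1)
  expect_equal(one$G[1], 8 * log(4))
  expect_error(gscores(tibble::tibble(gene_id = "a", L = 10, O = -1)),
               "negative")
  # expectation conservation on random inputs
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(3:30, 1)
    g <- gscores(tibble::tibble(gene_id = paste0("g", 1:n),
                                L = sample(100:2000, n, replace = TRUE),
                                O = rpois(n, 0.5)))
    expect_equal(sum(g$E), sum(g$O), tolerance = 1e-9)
    expect_true(all(is.finite(g$G)))
  }
})

test_that("Spearman correlation matches the permutation oracle", {
  inc <- spearman_correlation(1:5, c(2, 4, 6, 8, 10))
  expect_equal(inc$statistic, 1)
  dec <- spearman_correlation(1:5, 5:1)
  expect_equal(dec$statistic, -1)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")

  set.seed(21)
  for (rep in 1:5) {
    x <- sample(1:10, 6, replace = FALSE)
    y <- c(sample(1:8, 5, replace = FALSE), NA)
    y[6] <- y[1]  # plant a tie
    got <- spearman_correlation(x, y)
    want <- oracle_spearman(x, y)
    expect_equal(got$statistic, want$r)
    expect_equal(got$p_value, want$p)
  }
  # large-n branch: p is a valid probability and r matches cor on ranks
  x <- rnorm(50); y <- x + rnorm(50)
  big <- spearman_correlation(x, y)
  expect_equal(big$statistic, cor(rank(x), rank(y)))
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("Mann-Whitney U matches pair counting and enumeration", {
  allties <- mann_whitney(c(3, 3), c(3, 3, 3))
  expect_equal(allties$statistic, 2 * 3 / 2)

  below <- mann_whitney(c(1, 2), c(5, 6, 7))
  expect_equal(below$statistic, 0)

  set.seed(33)
  for (rep in 1:5) {
    a <- sample(1:20, 5, replace = TRUE)
    b <- sample(1:20, 4, replace = TRUE)
    got <- mann_whitney(a, b)
    expect_equal(got$statistic, oracle_u(a, b))
    expect_equal(got$p_value, oracle_u_p(a, b))
    # U_a + U_b = n_a * n_b
    expect_equal(got$statistic + mann_whitney(b, a)$statistic, 20)
  }
  # large-sample branch returns a valid probability
  big <- mann_whitney(rnorm(40), rnorm(40) + 0.5)
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("Wilcoxon signed-rank matches sign enumeration", {
  # antisymmetric differences: two-tailed p = 1 by symmetry
  a <- c(1, 2, 3, 4); b <- c(2, 1, 5, 2)   # d = -1, 1, -2, 2
  expect_equal(wilcoxon_signed_rank(a, b)$p_value, 1)

  set.seed(44)
  for (rep in 1:5) {
    x <- sample(1:30, 6, replace = TRUE)
    y <- sample(1:30, 6, replace = TRUE)
    if (all(x == y)) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, oracle_wilcoxon_p(x, y))
  }

  # all differences one-sided at n = 15: W takes an extreme value
  x <- 1:15; y <- x + 1
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$statistic, 0)
  expect_equal(res$n1, 15L)
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "all paired differences")

  # large-sample branch
  big <- wilcoxon_signed_rank(rnorm(50), rnorm(50) - 0.3)
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("Welch's t follows the textbook formula", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3); b <- a + 1
  got <- welch_t(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(got$statistic, (mean(a) - mean(b)) / se)
  df_want <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(got$df, df_want)

  # swapping groups negates t, p unchanged
  swapped <- welch_t(b, a)
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p_value, got$p_value)
  expect_error(welch_t(c(2, 2), c(2, 2)), "constant")
})

test_that("one-tailed Fisher's exact test equals hypergeometric enumeration", {
  for (x in c(0, 2, 5, 10, 20, 24)) {
    m <- matrix(c(2, 14, x, 40 - x), nrow = 2, byrow = TRUE)
    for (dir in c("less", "greater")) {
      expect_equal(fisher_exact_one_tailed(m, dir)$p_value,
                   oracle_fisher_one_tailed(m, dir),
                   tolerance = 1e-9)
    }
  }
  # proportional rows: no association in either direction
  prop <- matrix(c(10, 20, 5, 10), nrow = 2, byrow = TRUE)
  expect_gte(fisher_exact_one_tailed(prop, "greater")$p_value, 0.5)
  # degenerate margin
  degen <- fisher_exact_one_tailed(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(degen$p_value, 1)
  expect_true(degen$degenerate)
})

test_that("bootstrap median CI is reproducible and covers", {
  const <- bootstrap_median_ci(rep(5, 10), n_boot = 500, seed = 1)
  expect_equal(const$ci_low, 5)
  expect_equal(const$ci_high, 5)

  x <- rnorm(30)
  r1 <- bootstrap_median_ci(x, n_boot = 2000, seed = 99)
  r2 <- bootstrap_median_ci(x, n_boot = 2000, seed = 99)
  expect_identical(r1, r2)
  expect_true(r1$ci_low <= r1$median && r1$median <= r1$ci_high)
  expect_warning(bootstrap_median_ci(x, n_boot = 50, seed = 1), "unstable")
  expect_error(bootstrap_median_ci(1, n_boot = 500, seed = 1), "two values")

  # coverage close to nominal on normal samples
  set.seed(2024)
  covered <- 0
  for (i in 1:200) {
    smp <- rnorm(40)
    ci <- bootstrap_median_ci(smp, n_boot = 400, seed = i)
    if (ci$ci_low <= 0 && 0 <= ci$ci_high) covered <- covered + 1
  }
  expect_gte(covered / 200, 0.9)
})
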