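# preserve the caller's RNG state while running seeded code
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

rank_test_result <- function(method, statistic, p_value, sidedness, n1,
                             n2 = NA_integer_, ...) {
  tibble::tibble(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), sidedness = sidedness,
                 n1 = n1, n2 = n2, ...)
}

#' Compartment enrichment odds ratio and exact binomial test
#'
#' Quantifies over- or under-representation of a mutation category in the
#' core genome relative to the flexible genome. The headline `odds_ratio` is
#' the raw count ratio `core_n / flex_n` (>1 means over-represented in the
#' core); `rate_ratio` is the length-normalized per-bp alternative
#' `(core_n/L_core) / (flex_n/L_flex)`. The p-value is an exact two-tailed
#' binomial test of `core_n` successes in `core_n + flex_n` trials against
#' the length-based expectation `p0 = L_core / (L_core + L_flex)`, using the
#' minimum-likelihood two-sided rule (outcomes no more likely than the
#' observation).
#'
#' @param core_n,flex_n Mutation counts per compartment.
#' @param L_core,L_flex Compartment coding lengths in bp.
#' @return Tibble with `core_n`, `flex_n`, `odds_ratio`, `rate_ratio`, `p0`,
#'   `p_binomial_two_tailed`. `odds_ratio` is `NA` (undefined) when
#'   `flex_n = 0`; the p-value is still computed.
#' @export
enrichment_test <- function(core_n, flex_n, L_core, L_flex) {
  stopifnot(core_n >= 0, flex_n >= 0, core_n + flex_n > 0,
            L_core > 0, L_flex > 0)
  p0 <- L_core / (L_core + L_flex)
  tibble::tibble(
    core_n = core_n, flex_n = flex_n,
    odds_ratio = if (flex_n > 0) core_n / flex_n else NA_real_,
    rate_ratio = if (flex_n > 0) (core_n / L_core) / (flex_n / L_flex) else NA_real_,
    p0 = p0,
    p_binomial_two_tailed =
      stats::binom.test(core_n, core_n + flex_n, p = p0)$p.value
  )
}

#' Count-based dN/dS
#'
#' The ratio of nonsynonymous to synonymous mutation counts normalized by
#' the genome-wide ratio of nonsynonymous to synonymous sites at risk,
#' `dnds = (nonsyn_n / syn_n) / rho`.
#'
#' @param nonsyn_n,syn_n Mutation counts; `syn_n` must be positive.
#' @param rho Nonsynonymous-to-synonymous site ratio (default 3.22; see
#'   [site_ratio()] to compute it from sequences).
#' @return Tibble with `nonsyn_n`, `syn_n`, `rho`, `dnds`.
#' @export
dnds_ratio <- function(nonsyn_n, syn_n, rho = 3.22) {
  stopifnot(nonsyn_n >= 0, rho > 0)
  if (syn_n <= 0) stop("dN/dS undefined: syn_n must be positive")
  tibble::tibble(nonsyn_n = nonsyn_n, syn_n = syn_n, rho = rho,
                 dnds = (nonsyn_n / syn_n) / rho)
}

#' Gene-level parallelism G scores
#'
#' For each gene, compares the observed number of independent nonsynonymous
#' mutations `O_i` (in lineages with the ancestral mutation rate) with the
#' expectation `E_i = T * L_i / sum(L)` under a mutation rate proportional
#' to coding length, where `T = sum(O_i)`. The score `G_i = 2 * O_i *
#' ln(O_i / E_i)` (0 when `O_i = 0`, the `x ln x` limit) measures, in a
#' likelihood framework, the excess of repeated hits consistent with
#' positive selection.
#'
#' @param genes Tibble with columns `gene_id`, `L` (coding length bp, > 0)
#'   and `O` (observed hits, >= 0).
#' @return Tibble `gene_id`, `L`, `O`, `E`, `G`; `sum(E)` equals `sum(O)`.
#' @export
gscores <- function(genes) {
  stopifnot(all(c("gene_id", "L", "O") %in% names(genes)),
            all(genes$L > 0))
  if (any(genes$O < 0)) stop("negative observed counts")
  T_total <- sum(genes$O)
  E <- T_total * genes$L / sum(genes$L)
  G <- ifelse(genes$O == 0, 0, 2 * genes$O * log(genes$O / E))
  tibble::tibble(gene_id = genes$gene_id, L = genes$L, O = genes$O,
                 E = E, G = G)
}

# all permutations of 1..n as an n! x n matrix (used for exact small-n
# rank-correlation p-values)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The two-tailed p-value is
#' exact (full permutation enumeration) for `n <= exact_n_max`, and uses the
#' t approximation `t = r * sqrt((n-2)/(1-r^2))` otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact_n_max Largest n for exact enumeration (default 8).
#' @return A rank-test tibble (`method`, `statistic` = r, `p_value`,
#'   `sidedness`, `n1`).
#' @export
spearman_correlation <- function(x, y, exact_n_max = 8L) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("rank correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- permutations_of(n)
    null_r <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_r) >= abs(r) - 1e-12)
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(1, p)
  }
  rank_test_result("spearman", r, p, "two-tailed", n)
}

# U statistic for group a by pooled average ranks (equals pair counting with
# ties scored 1/2)
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' The U statistic counts, over all cross-group pairs, how often a value of
#' group a exceeds one of group b (ties score 1/2). The two-tailed p-value
#' is exact within `n_a * n_b <= exact_cap`: by full enumeration of group
#' assignments when feasible (handles ties), or from the exact tie-free U
#' distribution otherwise; beyond the cap a normal approximation with tie
#' correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact_cap Product cap for the exact branch (default 400).
#' @return A rank-test tibble (`statistic` = U for group a).
#' @export
mann_whitney <- function(group_a, group_b, exact_cap = 400L) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na > 0L, nb > 0L)
  u <- u_statistic(group_a, group_b)
  mu <- na * nb / 2
  pooled <- c(group_a, group_b)
  has_ties <- anyDuplicated(pooled) > 0L
  n <- na + nb
  if (na * nb <= exact_cap && choose(n, na) <= 2e5) {
    combs <- utils::combn(n, na)
    r <- rank(pooled)
    null_u <- apply(combs, 2L, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    p <- mean(abs(null_u - mu) >= abs(u - mu) - 1e-9)
  } else if (na * nb <= exact_cap && !has_ties) {
    p <- stats::wilcox.test(group_a, group_b, exact = TRUE)$p.value
  } else {
    tie_sizes <- table(pooled)
    sigma2 <- na * nb / 12 *
      (n + 1 - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
    if (sigma2 <= 0) stop("all pooled values identical; U test degenerate")
    p <- min(1, 2 * stats::pnorm(-abs(u - mu) / sqrt(sigma2)))
  }
  rank_test_result("mann_whitney", u, p, "two-tailed", na, nb)
}

#' Wilcoxon signed-rank test for paired values
#'
#' Differences of zero are dropped; the absolute differences are ranked with
#' average ranks for ties, and the statistic W is the sum of ranks of the
#' positive differences. The two-tailed p-value is exact (enumeration of all
#' 2^n sign assignments) for n <= `exact_n_max` nonzero differences, and a
#' normal approximation with tie correction beyond.
#'
#' @param paired_a,paired_b Numeric vectors of equal length.
#' @param exact_n_max Largest n for exact enumeration (default 15).
#' @return A rank-test tibble (`statistic` = W, `n1` = nonzero differences).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_n_max = 15L) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  s <- sum(r)
  if (n <= exact_n_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    null_w <- as.numeric(signs %*% r)
    p <- mean(abs(null_w - s / 2) >= abs(w - s / 2) - 1e-9)
  } else {
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- min(1, 2 * stats::pnorm(-abs(w - s / 2) / sqrt(sigma2)))
  }
  rank_test_result("wilcoxon_signed_rank", w, p, "two-tailed", n)
}

#' Welch's unequal-variance t test
#'
#' @param group_a,group_b Numeric vectors, each with at least two values.
#' @param sidedness `"two-tailed"`, `"greater"` (a > b) or `"less"`.
#' @return A rank-test tibble with an extra `df` column
#'   (Welch-Satterthwaite degrees of freedom).
#' @export
welch_t <- function(group_a, group_b,
                    sidedness = c("two-tailed", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    stop("both groups constant with equal means; t undefined")
  }
  alt <- switch(sidedness, "two-tailed" = "two.sided", greater = "greater",
                less = "less")
  ht <- stats::t.test(group_a, group_b, alternative = alt, var.equal = FALSE)
  rank_test_result("welch_t", ht$statistic, ht$p.value, sidedness,
                   length(group_a), length(group_b),
                   df = unname(ht$parameter))
}

#' One-tailed Fisher's exact test on a 2x2 table
#'
#' Hypergeometric tail probability in the configured direction. A table with
#' a zero row or column margin is degenerate: p = 1, flagged.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts.
#' @param direction `"greater"` or `"less"` association of cell (1,1).
#' @return A rank-test tibble (`statistic` = odds-ratio estimate) with an
#'   extra `degenerate` flag column.
#' @export
fisher_exact_one_tailed <- function(table_2x2,
                                    direction = c("greater", "less")) {
  direction <- match.arg(direction)
  m <- as.matrix(table_2x2)
  stopifnot(all(dim(m) == c(2L, 2L)), all(m >= 0), all(m == round(m)))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(rank_test_result("fisher_exact", NA_real_, 1, direction,
                            sum(m), degenerate = TRUE))
  }
  ht <- stats::fisher.test(m, alternative = direction)
  rank_test_result("fisher_exact", unname(ht$estimate), ht$p.value,
                   direction, sum(m), degenerate = FALSE)
}

#' Percentile bootstrap confidence interval for the median
#'
#' @param values Numeric vector with at least two values.
#' @param n_boot Number of bootstrap resamples (default 10000; fewer than
#'   100 triggers a warning).
#' @param seed Mandatory integer seed; the caller's RNG state is preserved.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `median`, `ci_low`, `ci_high`, `level`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000L, seed, level = 0.95) {
  if (length(values) < 2L) stop("need at least two values")
  if (missing(seed)) stop("seed is mandatory")
  if (n_boot < 100L) warning("n_boot < 100; interval will be unstable")
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stats::median(sample(values, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  tibble::tibble(median = stats::median(values), ci_low = ci[1],
                 ci_high = ci[2], level = level, n_boot = n_boot, seed = seed)
}
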