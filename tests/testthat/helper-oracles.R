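# Independent brute-force oracles. Deliberately naive implementations,
# kept free of any code path they are used to check.

# mean pairwise differences per site: explicit double loop over pairs and
# columns, residue-vs-gap is a difference, gap-gap skipped
oracle_pi_aa <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diffs <- 0; compared <- 0
    for (k in seq_len(ncol(m))) {
      a <- m[i, k]; b <- m[j, k]
      if (a == "-" && b == "-") next
      compared <- compared + 1
      if (a != b) diffs <- diffs + 1
    }
    vals <- c(vals, diffs / compared)
  }
  mean(vals)
}

# U statistic by explicit pair counting (ties = 1/2)
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  u
}

# exact two-tailed p of the U statistic by enumerating all group assignments
oracle_u_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  mu <- na * length(b) / 2
  u_obs <- oracle_u(a, b)
  combs <- utils::combn(n, na)
  hits <- 0
  for (c_i in seq_len(ncol(combs))) {
    idx <- combs[, c_i]
    u <- oracle_u(pooled[idx], pooled[-idx])
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / ncol(combs)
}

# exact two-tailed signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  s <- sum(r)
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    w <- sum(r[signs == 1])
    if (abs(w - s / 2) >= abs(w_obs - s / 2) - 1e-9) hits <- hits + 1
  }
  hits / 2^n
}

# all permutations of 1..n, built by simple recursion
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1, sub))
  }))
}

# exact two-tailed Spearman p by full permutation enumeration
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r_obs <- stats::cor(rx, ry)
  perms <- oracle_perms(length(x))
  null_r <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  list(r = r_obs, p = mean(abs(null_r) >= abs(r_obs) - 1e-12))
}

# minimum-likelihood two-sided binomial p by enumerating all outcomes
oracle_binom_two_tailed <- function(k, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# one-tailed Fisher p by hypergeometric enumeration over all tables with
# the observed margins
oracle_fisher_one_tailed <- function(m, direction) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- sapply(lo:hi, function(a) {
    stats::dhyper(a, r1, r2, c1)
  })
  a_obs <- m[1, 1]
  ks <- lo:hi
  if (direction == "greater") {
    sum(probs[ks >= a_obs])
  } else {
    sum(probs[ks <= a_obs])
  }
}

# brute-force minimum inter-atom distance between a residue and all partner
# atoms
oracle_min_distance <- function(atoms, chain_id, resno) {
  target <- atoms[atoms$chain == chain_id & atoms$resno == resno, ]
  partner <- atoms[atoms$chain != chain_id |
                     (atoms$is_hetero &
                        !(atoms$chain == chain_id & atoms$resno == resno)), ]
  best <- Inf
  for (i in seq_len(nrow(target))) for (j in seq_len(nrow(partner))) {
    d <- sqrt((target$x[i] - partner$x[j])^2 +
                (target$y[i] - partner$y[j])^2 +
                (target$z[i] - partner$z[j])^2)
    best <- min(best, d)
  }
  best
}

# random protein sequence over the 20 standard residues
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# random gapped alignment rows (equal width, no all-gap pair guaranteed by
# keeping column 1 gap-free)
random_alignment_rows <- function(n_seqs, n_cols, gap_prob = 0.15) {
  rows <- sapply(seq_len(n_seqs), function(i) {
    chars <- sample(c("A", "C", "D", "E"), n_cols, replace = TRUE)
    gaps <- runif(n_cols) < gap_prob
    gaps[1] <- FALSE
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  })
  names(rows) <- paste0("s", seq_len(n_seqs))
  rows
}

# tiny two-genome annotation + matching partition used by mutation tests
make_toy_reference <- function(seed = 101, n_core = 10L, n_flexible = 10L) {
  sim <- simulate_pangenome(pangenome_sim_config(
    n_genomes = 2L, n_core = n_core, n_flexible = n_flexible,
    flexible_presence_prob = 1, force_absence = FALSE,
    indel_prob = 0, seed = seed
  ))
  ref <- sim$genomes[[1]]
  truth <- sim$truth[sim$truth$genome_id == ref$genome_id, ]
  partition <- core_partition(tibble::tibble(
    gene_id = ref$genes$gene_id,
    compartment = truth$compartment[match(ref$genes$gene_id, truth$gene_id)],
    length_bp = nchar(ref$genes$nt_seq)
  ))
  list(annotation = ref, partition = partition, truth = truth)
}
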