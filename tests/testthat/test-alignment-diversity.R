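test_that("align_family handles identity, gaps, and validates inputs", {
  a <- align_family(c(x = "MKVLAT", y = "MKVLAT"))
  expect_equal(unname(a$rows), c("MKVLAT", "MKVLAT"))
  expect_equal(a$n_columns, 6L)

  b <- align_family(c(x = "ACDE", y = "ACE"))
  expect_equal(b$n_columns, 4L)
  expect_equal(gsub("-", "", b$rows[["y"]]), "ACE")
  expect_equal(sum(strsplit(b$rows[["y"]], "")[[1]] == "-"), 1L)

  expect_error(align_family(c(x = "ACDE")), "at least 2")
  expect_error(align_family(c(x = "AC1E", y = "ACE")), "non-residue")
})

test_that("center-star alignment of several sequences preserves inputs", {
  set.seed(5)
  for (rep in 1:5) {
    base <- random_protein(30)
    seqs <- setNames(c(base, vapply(1:3, function(i) {
      ch <- strsplit(base, "")[[1]]
      ch[sample(30, 2)] <- "W"
      if (i == 2) ch <- ch[-(10:12)]
      paste(ch, collapse = "")
    }, character(1))), paste0("s", 1:4))
    aln <- align_family(seqs)
    expect_equal(unname(nchar(aln$rows)), rep(aln$n_columns, 4))
    expect_equal(unname(gsub("-", "", aln$rows)), unname(seqs))
  }
})

test_that("pre-aligned FASTA loads and validates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-DE", ">b", "ACWDE"), path)
  aln <- load_alignment(path, originals = c(a = "ACDE", b = "ACWDE"))
  expect_equal(aln$n_columns, 5L)
  expect_error(load_alignment(path, originals = c(a = "ACDE", b = "ACWDQ")),
               "do not reproduce")
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC-DE", ">b", "ACW"), bad)
  expect_error(load_alignment(bad), "differ in length")
})

test_that("pi_aa follows the per-pair indel-counting convention", {
  # all identical: zero diversity
  same <- protein_alignment(c(a = "MKVL", b = "MKVL", c = "MKVL"))
  expect_equal(pairwise_aa_diversity(same)$pi_aa, 0)

  # a 10-residue indel over 110 columns counts as 10 differences
  r1 <- paste(rep("A", 110), collapse = "")
  r2 <- paste(c(rep("A", 50), rep("-", 10), rep("A", 50)), collapse = "")
  rec <- pairwise_divergence(protein_alignment(c(a = r1, b = r2)))
  expect_equal(rec$n_diff, 10)
  expect_equal(rec$aligned_length, 110)

  # 60 sequences yield 60 * 59 / 2 = 1770 pairs
  many <- protein_alignment(setNames(rep("MKV", 60), paste0("s", 1:60)))
  expect_equal(pairwise_aa_diversity(many)$n_pairs, 1770)

  # hand-enumerated toy: pairs give 1/4, 2/4, 1/4 -> mean 1/3
  toy <- protein_alignment(c(a = "AAAA", b = "AABA", c = "A-BA"))
  expect_equal(pairwise_aa_diversity(toy)$pi_aa, 1 / 3)

  # a pair sharing zero compared columns is an error naming the pair
  # (residue-vs-gap columns count as compared, so only jointly all-gap
  # rows trigger this)
  bad <- protein_alignment(c(a = "----", b = "----", c = "AAAA"))
  expect_error(pairwise_aa_diversity(bad), "zero compared columns")
})

test_that("pi_aa equals the brute-force oracle and is permutation invariant", {
  set.seed(31)
  for (rep in 1:20) {
    rows <- random_alignment_rows(sample(2:5, 1), sample(4:20, 1))
    res <- try(pairwise_aa_diversity(protein_alignment(rows)), silent = TRUE)
    if (inherits(res, "try-error")) next  # zero-overlap pair; oracle agrees it's degenerate
    expect_equal(res$pi_aa, oracle_pi_aa(rows))

    # row reordering and column permutation leave pi_aa unchanged
    perm_cols <- sample(nchar(rows[1]))
    shuffled <- vapply(rows, function(r) {
      paste(strsplit(r, "")[[1]][perm_cols], collapse = "")
    }, character(1))
    expect_equal(
      pairwise_aa_diversity(protein_alignment(shuffled[sample(length(rows))]))$pi_aa,
      res$pi_aa
    )
  }
})

test_that("site-partitioned diversity restricts correctly", {
  inv <- protein_alignment(c(a = "MMMM", b = "MMMM", c = "MMMM"))
  res <- partition_site_diversity(inv, target_columns = c(1, 2))
  expect_equal(res$pi_target, 0)
  expect_equal(res$pi_rest, 0)

  # all variation planted in the target columns
  planted <- protein_alignment(c(a = "WAMM", b = "CAMM", c = "DAMM"))
  res2 <- partition_site_diversity(planted, target_columns = 1L)
  expect_gt(res2$pi_target, 0)
  expect_equal(res2$pi_rest, 0)

  # restriction to all columns reproduces pi_aa
  set.seed(77)
  rows <- random_alignment_rows(4, 12, gap_prob = 0)
  aln <- protein_alignment(rows)
  expect_equal(partition_site_diversity(aln, 1:12)$pi_target,
               pairwise_aa_diversity(aln)$pi_aa)

  # column-subset brute force on a random gapped toy
  rows5 <- random_alignment_rows(5, 10)
  aln5 <- protein_alignment(rows5)
  cols <- c(2, 5, 7)
  sub_rows <- vapply(rows5, function(r) {
    paste(strsplit(r, "")[[1]][cols], collapse = "")
  }, character(1))
  got <- partition_site_diversity(aln5, cols)
  expect_equal(got$pi_target, oracle_pi_aa(sub_rows))

  expect_error(partition_site_diversity(aln, 99L), "out of range")
  expect_error(partition_site_diversity(aln, integer(0)), "empty")
})

test_that("residue-to-column mapping inverts ungapped counting", {
  plain <- protein_alignment(c(a = "MKVL", b = "MKVL"))
  expect_equal(map_residue_to_column(plain, "a", 3L), 3L)

  gapped <- protein_alignment(c(a = "-AC", b = "WAC"))
  expect_equal(map_residue_to_column(gapped, "a", 1L), 2L)
  expect_error(map_residue_to_column(gapped, "a", 5L), "out of range")

  # round trip: column k of row holds exactly the residue mapped to it
  set.seed(91)
  for (rep in 1:10) {
    rows <- random_alignment_rows(2, 15)
    aln <- protein_alignment(rows)
    chars <- strsplit(rows[[1]], "")[[1]]
    n_res <- sum(chars != "-")
    if (n_res == 0) next
    for (i in seq_len(n_res)) {
      col <- map_residue_to_column(aln, "s1", i)
      expect_equal(sum(chars[1:col] != "-"), i)
    }
  }
})

test_that("pairwise divergence follows the shared gap conventions", {
  ident <- protein_alignment(c(a = "MKVL", b = "MKVL"))
  expect_equal(pairwise_divergence(ident)$d, 0)

  r1 <- paste(rep("A", 100), collapse = "")
  r2 <- paste(c(rep("A", 50), "W", "W", rep("A", 48)), collapse = "")
  expect_equal(pairwise_divergence(protein_alignment(c(a = r1, b = r2)))$d, 0.02)

  # one 3-column indel plus 1 mismatch over 50 columns: d = 4/50
  a50 <- paste(rep("A", 50), collapse = "")
  b50 <- paste(c(rep("A", 20), rep("-", 3), "W", rep("A", 26)), collapse = "")
  expect_equal(pairwise_divergence(protein_alignment(c(a = a50, b = b50)))$d,
               4 / 50)
})

test_that("expected diversity rises with the generator substitution rate", {
  rates <- c(0.005, 0.03, 0.12)
  mean_pi <- vapply(seq_along(rates), function(k) {
    sim <- simulate_pangenome(pangenome_sim_config(
      n_genomes = 4, n_core = 12, n_flexible = 0, indel_prob = 0,
      per_site_substitution_prob = rates[k], seed = 500 + k
    ))
    fams <- split(sim$truth$gene_id, sim$truth$family_id)
    prots <- unlist(unname(lapply(sim$genomes, proteome)))
    mean(vapply(fams, function(gids) {
      aln <- align_family(setNames(prots[gids], gids))
      pairwise_aa_diversity(aln)$pi_aa
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_pi) > 0))
})
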