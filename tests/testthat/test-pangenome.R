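test_that("score_all_pairs finds identity hits and respects thresholds", {
  p <- c(gA = "MKVLATTPFGGRSDEW")
  q <- c(gB = "MKVLATTPFGGRSDEW")
  hits <- score_all_pairs(p, q)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$coverage, 1.0)

  # unrelated protein below thresholds yields no hits for that query
  r <- c(gC = "WWWWHHHHCCCCNNNNYYYY")
  expect_equal(nrow(score_all_pairs(p, r)), 0L)

  # empty input is an empty result, not an error
  expect_equal(nrow(score_all_pairs(character(0), q)), 0L)
})

test_that("score_all_pairs recovers planted family pairs among decoys", {
  set.seed(421)
  # three families: near-identical pairs across genomes, plus decoys
  fams <- replicate(3, random_protein(60))
  mutate_one <- function(s, k = 3) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), k)
    ch[at] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], k, replace = TRUE)
    paste(ch, collapse = "")
  }
  a <- setNames(fams, paste0("a", 1:3))
  b <- setNames(vapply(fams, mutate_one, character(1)), paste0("b", 1:3))
  decoys <- setNames(replicate(3, random_protein(60)), paste0("d", 1:3))
  hits <- score_all_pairs(a, c(b, decoys),
                          scorer_config(min_identity = 0.5, min_coverage = 0.5))
  # exactly the three planted pairs pass
  expect_equal(sort(paste(hits$query_gene_id, hits$subject_gene_id)),
               c("a1 b1", "a2 b2", "a3 b3"))
})

test_that("reciprocal_best_hits keeps symmetric best pairs only", {
  h <- function(q, s, score) {
    tibble::tibble(query_gene_id = q, subject_gene_id = s, score = score,
                   identity = 0.9, coverage = 1)
  }
  # symmetric best hits
  expect_equal(
    reciprocal_best_hits(h("a", "b", 100), h("b", "a", 100)),
    tibble::tibble(gene_a = "a", gene_b = "b")
  )
  # a's best is b, but b's best is a2: excluded
  ab <- h("a", "b", 100)
  ba <- dplyr::bind_rows(h("b", "a", 90), h("b", "a2", 95))
  expect_equal(nrow(reciprocal_best_hits(ab, ba)), 0L)
  # duplicate guard: tie for the top score disqualifies the query
  ab_tie <- dplyr::bind_rows(h("a", "b1", 100), h("a", "b2", 100))
  ba_ok <- dplyr::bind_rows(h("b1", "a", 100), h("b2", "a", 100))
  expect_equal(nrow(reciprocal_best_hits(ab_tie, ba_ok)), 0L)
  # empty inputs give an empty set
  expect_equal(nrow(reciprocal_best_hits(ab[0, ], ba[0, ])), 0L)
})

make_mini_collection <- function(seed, ...) {
  sim <- simulate_pangenome(pangenome_sim_config(seed = seed, ...))
  prots <- lapply(sim$genomes, proteome)
  ids <- names(sim$genomes)
  hits <- list()
  for (qa in ids) for (qb in ids) {
    hits[[paste(qa, qb, sep = "|")]] <-
      score_all_pairs(prots[[qa]], prots[[qb]])
  }
  rbh <- list()
  for (pair in utils::combn(sort(ids), 2L, simplify = FALSE)) {
    rbh[[paste(pair, collapse = "|")]] <- reciprocal_best_hits(
      hits[[paste(pair[1], pair[2], sep = "|")]],
      hits[[paste(pair[2], pair[1], sep = "|")]]
    )
  }
  list(sim = sim, hits = hits, rbh = rbh)
}

test_that("panortholog groups recover the planted core families exactly", {
  mc <- make_mini_collection(seed = 77, n_genomes = 4, n_core = 8,
                             n_flexible = 4)
  groups <- build_panortholog_set(mc$sim$genomes, mc$rbh, mc$hits)
  core_fams <- unique(mc$sim$truth$family_id[mc$sim$truth$compartment == "core"])
  # precision = recall = 1 against the generator truth
  recovered <- split(groups$gene_id, groups$family_id)
  truth_sets <- split(mc$sim$truth$gene_id[mc$sim$truth$compartment == "core"],
                      mc$sim$truth$family_id[mc$sim$truth$compartment == "core"])
  expect_equal(length(recovered), length(core_fams))
  expect_setequal(
    unname(vapply(recovered, function(g) paste(sort(g), collapse = ","),
                  character(1))),
    unname(vapply(truth_sets, function(g) paste(sort(g), collapse = ","),
                  character(1)))
  )

  # classification matches truth labels perfectly, and length is conserved
  ref <- mc$sim$genomes[[1]]
  part <- classify_core_flexible(ref, groups)
  truth_ref <- mc$sim$truth[mc$sim$truth$genome_id == ref$genome_id, ]
  expect_equal(
    part$genes$compartment,
    truth_ref$compartment[match(part$genes$gene_id, truth_ref$gene_id)]
  )
  expect_equal(part$L_core + part$L_flex, ref$total_coding_length)
})

test_that("panortholog construction is order independent", {
  mc <- make_mini_collection(seed = 78, n_genomes = 3, n_core = 5,
                             n_flexible = 3)
  g1 <- build_panortholog_set(mc$sim$genomes, mc$rbh, mc$hits)
  g2 <- build_panortholog_set(rev(mc$sim$genomes), mc$rbh, mc$hits)
  key <- function(g) {
    sort(vapply(split(g$gene_id, g$family_id),
                function(x) paste(sort(x), collapse = ","), character(1)))
  }
  expect_equal(unname(key(g1)), unname(key(g2)))
})

test_that("groups missing a genome are discarded and missing RBH sets error", {
  mc <- make_mini_collection(seed = 79, n_genomes = 3, n_core = 4,
                             n_flexible = 2, flexible_presence_prob = 0.5)
  groups <- build_panortholog_set(mc$sim$genomes, mc$rbh, mc$hits)
  # flexible families (absent somewhere) never form a panortholog group
  flex_genes <- mc$sim$truth$gene_id[mc$sim$truth$compartment == "flexible"]
  expect_length(intersect(groups$gene_id, flex_genes), 0L)

  rbh_missing <- mc$rbh[-1]
  expect_error(build_panortholog_set(mc$sim$genomes, rbh_missing, mc$hits),
               names(mc$rbh)[1], fixed = TRUE)
})

test_that("RBH pairs are a subset of the top-1 hit graph", {
  set.seed(991)
  for (rep in 1:5) {
    a <- setNames(replicate(6, random_protein(40)), paste0("a", 1:6))
    b <- c(setNames(vapply(a[1:4], function(s) s, character(1)),
                    paste0("b", 1:4)),
           setNames(replicate(2, random_protein(40)), paste0("b", 5:6)))
    scorer <- scorer_config(min_identity = 0.3)
    hab <- score_all_pairs(a, b, scorer)
    hba <- score_all_pairs(b, a, scorer)
    pairs <- reciprocal_best_hits(hab, hba)
    if (nrow(pairs) == 0L) next
    for (i in seq_len(nrow(pairs))) {
      mine <- hab[hab$query_gene_id == pairs$gene_a[i], ]
      expect_equal(pairs$gene_b[i],
                   mine$subject_gene_id[which.max(mine$score)])
    }
  }
})

test_that("classify_core_flexible handles degenerate and error cases", {
  mc <- make_mini_collection(seed = 80, n_genomes = 3, n_core = 5,
                             n_flexible = 0)
  groups <- build_panortholog_set(mc$sim$genomes, mc$rbh, mc$hits)
  part <- classify_core_flexible(mc$sim$genomes[[1]], groups)
  expect_equal(part$L_flex, 0)
  expect_equal(length(part$flexible_gene_ids), 0L)

  other <- genome_annotation("zz", mc$sim$genomes[[2]]$genes |>
                               dplyr::mutate(genome_id = "zz"))
  expect_error(classify_core_flexible(other, groups), "absent")
})

test_that("one-to-one interspecies calls intersect as plain sets", {
  p1 <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "d"))
  p2 <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "e"))
  expect_equal(intersect_ortholog_calls(p1, p1), p1)
  expect_equal(nrow(intersect_ortholog_calls(
    p1, tibble::tibble(gene_a = "x", gene_b = "y"))), 0L)
  expect_equal(intersect_ortholog_calls(p1, p2),
               tibble::tibble(gene_a = "a", gene_b = "b"))

  # two-genome RBH via the same rules
  s <- c(x1 = "MKVLATTPFGGRSDEW", x2 = "HHHHCCCCNNNNYYYY")
  t_ <- c(y1 = "MKVLATTPFGGRSDEW", y2 = "HHHHCCCCNNNNYYYY")
  pairs <- one_to_one_interspecies(s, t_)
  expect_equal(pairs, tibble::tibble(gene_a = c("x1", "x2"),
                                     gene_b = c("y1", "y2")))
})
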