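#' @importFrom rlang .data
NULL

# Per-pair difference and comparison counts over a column subset.
# Conventions: a residue-vs-gap column is a difference (each indel column
# counts separately); gap-vs-gap columns are skipped for that pair.
pair_diff_stats <- function(m, cols) {
  n <- nrow(m)
  pairs <- utils::combn(n, 2L)
  t(apply(pairs, 2L, function(ij) {
    a <- m[ij[1], cols]; b <- m[ij[2], cols]
    compared <- !(a == "-" & b == "-")
    c(i = ij[1], j = ij[2],
      n_diff = sum(compared & a != b), n_compared = sum(compared))
  }))
}

#' Mean pairwise amino-acid diversity of an aligned family
#'
#' Amino-acid analogue of Nei's nucleotide diversity: for every unordered
#' pair of rows, count the columns where the two symbols differ — with a
#' residue opposite a gap counted as a difference, so an indel spanning 10
#' residues contributes 10 differences — divide by the columns compared for
#' that pair (gap-vs-gap columns skipped), and average over all
#' n(n-1)/2 pairs. With `normalization = "pooled"` the totals are pooled
#' across pairs before dividing instead.
#'
#' @param alignment A `protein_alignment`.
#' @param normalization `"per_pair"` (default: mean of per-pair per-site
#'   values) or `"pooled"` (summed differences / summed compared columns).
#' @return A tibble with `gene_id`, `n_seqs`, `n_pairs`, `pi_aa`, and a
#'   `per_column_diff_counts` list-column (number of differing pairs at each
#'   column).
#' @export
pairwise_aa_diversity <- function(alignment, normalization = c("per_pair", "pooled")) {
  normalization <- match.arg(normalization)
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  stopifnot(n >= 2L)
  st <- pair_diff_stats(m, seq_len(ncol(m)))
  if (any(st[, "n_compared"] == 0L)) {
    bad <- which(st[, "n_compared"] == 0L)[1]
    stop("pair (", names(alignment$rows)[st[bad, "i"]], ", ",
         names(alignment$rows)[st[bad, "j"]], ") shares zero compared columns")
  }
  pi_aa <- switch(normalization,
    per_pair = mean(st[, "n_diff"] / st[, "n_compared"]),
    pooled = sum(st[, "n_diff"]) / sum(st[, "n_compared"])
  )
  per_col <- vapply(seq_len(ncol(m)), function(k) {
    a <- m[st[, "i"], k]; b <- m[st[, "j"], k]
    sum(!(a == "-" & b == "-") & a != b)
  }, numeric(1))
  tibble::tibble(
    gene_id = alignment$family_id,
    n_seqs = n,
    n_pairs = n * (n - 1L) / 2L,
    pi_aa = pi_aa,
    per_column_diff_counts = list(per_col)
  )
}

#' Site-partitioned diversity
#'
#' Computes the pairwise amino-acid diversity separately over a target set
#' of alignment columns (for example, the sites mutated during an evolution
#' experiment) and over the complementary columns, under the same per-pair
#' gap conventions as [pairwise_aa_diversity()]. Pairs sharing no compared
#' column within a subset contribute nothing to its mean.
#'
#' @param alignment A `protein_alignment`.
#' @param target_columns Integer vector of column indices (non-empty, within
#'   range).
#' @param normalization Passed through to the per-subset computation.
#' @return Tibble with `gene_id`, `n_target_sites`, `pi_target`, `pi_rest`.
#' @export
partition_site_diversity <- function(alignment, target_columns,
                                     normalization = c("per_pair", "pooled")) {
  normalization <- match.arg(normalization)
  target_columns <- sort(unique(as.integer(target_columns)))
  if (length(target_columns) == 0L) stop("target_columns is empty")
  if (any(target_columns < 1L | target_columns > alignment$n_columns)) {
    stop("target column(s) out of range 1..", alignment$n_columns)
  }
  m <- alignment_matrix(alignment)
  subset_pi <- function(cols) {
    if (length(cols) == 0L) return(NA_real_)
    st <- pair_diff_stats(m, cols)
    ok <- st[, "n_compared"] > 0L
    if (!any(ok)) return(NA_real_)
    switch(normalization,
      per_pair = mean(st[ok, "n_diff"] / st[ok, "n_compared"]),
      pooled = sum(st[ok, "n_diff"]) / sum(st[ok, "n_compared"])
    )
  }
  tibble::tibble(
    gene_id = alignment$family_id,
    n_target_sites = length(target_columns),
    pi_target = subset_pi(target_columns),
    pi_rest = subset_pi(setdiff(seq_len(alignment$n_columns), target_columns))
  )
}

#' Interspecies divergence of an aligned ortholog pair
#'
#' The proportion of aligned residues that differ between the two proteins,
#' with the same gap conventions as [pairwise_aa_diversity()]: each column of
#' an indel counts as one difference and gap-vs-gap columns are skipped.
#'
#' @param alignment A two-row `protein_alignment`.
#' @return Tibble with `gene_id`, `aligned_length` (columns compared),
#'   `n_diff`, `d`.
#' @export
pairwise_divergence <- function(alignment) {
  m <- alignment_matrix(alignment)
  if (nrow(m) != 2L) stop("pairwise_divergence needs a two-row alignment")
  st <- pair_diff_stats(m, seq_len(ncol(m)))
  if (st[1, "n_compared"] == 0L) stop("zero compared columns in pair")
  tibble::tibble(
    gene_id = alignment$family_id,
    aligned_length = unname(st[1, "n_compared"]),
    n_diff = unname(st[1, "n_diff"]),
    d = unname(st[1, "n_diff"] / st[1, "n_compared"])
  )
}
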