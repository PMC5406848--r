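#' Similarity scorer configuration
#'
#' The default scorer is global (Needleman-Wunsch) protein alignment with the
#' BLOSUM62 matrix. Identity is matches divided by alignment columns;
#' coverage is the fraction of query residues inside the aligned region
#' (always 1 under global alignment, retained so a local scorer can be
#' substituted). Hits below either threshold are dropped.
#'
#' @param min_identity,min_coverage Acceptance thresholds in `[0, 1]`.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @param substitution_matrix Name of a Biostrings substitution matrix.
#' @return A list of class `scorer_config`.
#' @export
scorer_config <- function(min_identity = 0.5, min_coverage = 0.5,
                          gap_opening = 10, gap_extension = 0.5,
                          substitution_matrix = "BLOSUM62") {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 gap_opening = gap_opening, gap_extension = gap_extension,
                 substitution_matrix = substitution_matrix),
            class = "scorer_config")
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

empty_hits <- function() {
  tibble::tibble(query_gene_id = character(), subject_gene_id = character(),
                 score = numeric(), identity = numeric(), coverage = numeric())
}

#' All-vs-all protein similarity search between two genomes
#'
#' Aligns every query protein of genome A against every protein of genome B
#' and returns the hits passing the configured identity and coverage
#' thresholds, sorted by descending score within each query. Deterministic
#' for fixed inputs. Sequences containing characters outside the amino-acid
#' alphabet are rejected with a warning.
#'
#' @param proteins_a,proteins_b Named character vectors of protein sequences
#'   (names are gene ids).
#' @param scorer A [scorer_config()].
#' @return Tibble with columns `query_gene_id`, `subject_gene_id`, `score`,
#'   `identity`, `coverage`.
#' @export
score_all_pairs <- function(proteins_a, proteins_b, scorer = scorer_config()) {
  if (length(proteins_a) == 0L || length(proteins_b) == 0L) return(empty_hits())
  ok_a <- grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", proteins_a)
  ok_b <- grepl("^[ACDEFGHIKLMNPQRSTVWYX*]+$", proteins_b)
  if (!all(ok_a)) {
    warning("rejecting query protein(s) with invalid residues: ",
            paste(names(proteins_a)[!ok_a], collapse = ", "))
    proteins_a <- proteins_a[ok_a]
  }
  if (!all(ok_b)) {
    warning("rejecting subject protein(s) with invalid residues: ",
            paste(names(proteins_b)[!ok_b], collapse = ", "))
    proteins_b <- proteins_b[ok_b]
  }
  if (length(proteins_a) == 0L || length(proteins_b) == 0L) return(empty_hits())

  mat <- get_substitution_matrix(scorer$substitution_matrix)
  # identity = matches / columns <= min(len) / max(len) under global
  # alignment, so pairs below the identity threshold on length ratio alone
  # can be skipped without aligning
  la <- nchar(proteins_a); lb <- nchar(proteins_b)
  idx <- expand.grid(i = seq_along(proteins_a), j = seq_along(proteins_b))
  ratio <- pmin(la[idx$i], lb[idx$j]) / pmax(la[idx$i], lb[idx$j])
  idx <- idx[ratio >= scorer$min_identity, , drop = FALSE]
  if (nrow(idx) == 0L) return(empty_hits())
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(proteins_a[idx$i]),
    subject = Biostrings::AAStringSet(proteins_b[idx$j]),
    substitutionMatrix = mat, gapOpening = scorer$gap_opening,
    gapExtension = scorer$gap_extension, type = "global"
  )
  n_col <- Biostrings::nchar(al)
  hits <- tibble::tibble(
    query_gene_id = names(proteins_a)[idx$i],
    subject_gene_id = names(proteins_b)[idx$j],
    score = Biostrings::score(al),
    identity = Biostrings::nmatch(al) / n_col,
    # end-to-end alignment always covers the query; a substituted local
    # scorer would compute this from its aligned range
    coverage = 1
  )
  hits <- dplyr::filter(hits, .data$identity >= scorer$min_identity,
                        .data$coverage >= scorer$min_coverage)
  dplyr::arrange(hits, .data$query_gene_id, dplyr::desc(.data$score),
                 .data$subject_gene_id)
}

# Unique top-scoring hit per query; queries whose top score is tied between
# two or more subjects are dropped (duplication guard).
unique_top_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble::tibble(query_gene_id = character(),
                          subject_gene_id = character(), score = numeric()))
  }
  hits |>
    dplyr::group_by(.data$query_gene_id) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::filter(dplyr::n() == 1L) |>
    dplyr::ungroup() |>
    dplyr::select("query_gene_id", "subject_gene_id", "score")
}

#' Reciprocal best hits between two genomes
#'
#' A pair (a, b) is reciprocal-best iff b is a's unique top-scoring hit in
#' genome B and a is b's unique top-scoring hit in genome A. A tie for the
#' top score disqualifies the query, guarding against recent duplications.
#'
#' @param hits_ab Hits with genome A queries and genome B subjects.
#' @param hits_ba Hits in the opposite direction.
#' @return Tibble with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  top_ab <- unique_top_hits(hits_ab)
  top_ba <- unique_top_hits(hits_ba)
  pairs <- dplyr::inner_join(
    dplyr::select(top_ab, gene_a = "query_gene_id", gene_b = "subject_gene_id"),
    dplyr::select(top_ba, gene_b = "query_gene_id", gene_a = "subject_gene_id"),
    by = c("gene_a", "gene_b")
  )
  dplyr::arrange(pairs, .data$gene_a)
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Build panortholog groups from pairwise reciprocal best hits
#'
#' Panortholog groups are connected components of the pooled RBH graph that
#' (i) contain exactly one gene from every genome, (ii) form a clique — every
#' cross-genome pair within the component is itself an RBH pair — and (iii),
#' when full hit tables are supplied, pass the best-local-hit guard: no
#' member may have a higher-scoring hit in any genome (including its own,
#' excluding itself) than its group partner there. All other components are
#' discarded.
#'
#' @param genomes List of `genome_annotation` objects.
#' @param rbh_sets Named list of RBH pair tables, one per unordered genome
#'   pair, named `"<idA>|<idB>"` with ids in sorted order; `gene_a` belongs
#'   to the alphabetically first genome of the key.
#' @param hits Optional named list of full hit tables keyed by ordered pair
#'   `"<query_genome>|<subject_genome>"`, used for the best-local-hit guard.
#' @return Tibble with columns `family_id`, `genome_id`, `gene_id`, one row
#'   per group member.
#' @export
build_panortholog_set <- function(genomes, rbh_sets, hits = NULL) {
  genome_ids <- vapply(genomes, function(g) g$genome_id, character(1))
  n_genomes <- length(genome_ids)
  expected <- utils::combn(sort(genome_ids), 2L,
                           FUN = function(p) paste(p, collapse = "|"))
  missing <- setdiff(expected, names(rbh_sets))
  if (length(missing) > 0L) {
    stop("missing RBH set(s) for genome pair(s): ", paste(missing, collapse = ", "))
  }

  gene_owner <- unlist(unname(lapply(genomes, function(g) {
    stats::setNames(rep(g$genome_id, nrow(g$genes)), g$genes$gene_id)
  })))

  # pooled RBH edge list, plus per-pair lookup for the clique check
  edges <- dplyr::bind_rows(lapply(expected, function(k) {
    rbh_sets[[k]][, c("gene_a", "gene_b")]
  }))
  if (nrow(edges) == 0L) {
    return(tibble::tibble(family_id = character(), genome_id = character(),
                          gene_id = character()))
  }
  edge_keys <- paste(pmin(edges$gene_a, edges$gene_b),
                     pmax(edges$gene_a, edges$gene_b), sep = "\r")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  members_by_comp <- split(names(comp$membership), comp$membership)

  keep <- list()
  fam <- 0L
  for (members in members_by_comp) {
    owners <- gene_owner[members]
    if (length(members) != n_genomes) next
    if (anyNA(owners) || anyDuplicated(owners) || length(unique(owners)) != n_genomes) next
    combs <- utils::combn(members, 2L)
    ck <- paste(pmin(combs[1, ], combs[2, ]), pmax(combs[1, ], combs[2, ]), sep = "\r")
    if (!all(ck %in% edge_keys)) next
    if (!is.null(hits) && !passes_best_hit_guard(members, owners, hits)) next
    fam <- fam + 1L
    keep[[fam]] <- tibble::tibble(
      family_id = sprintf("fam%04d", fam),
      genome_id = unname(owners),
      gene_id = members
    )
  }
  if (length(keep) == 0L) {
    return(tibble::tibble(family_id = character(), genome_id = character(),
                          gene_id = character()))
  }
  dplyr::arrange(dplyr::bind_rows(keep), .data$family_id, .data$genome_id)
}

# TRUE unless some member has a strictly better hit in another genome than
# its group partner there, or a within-genome hit (to another gene) beating
# the weakest partner score.
passes_best_hit_guard <- function(members, owners, hits) {
  partner_of <- stats::setNames(members, owners)
  for (i in seq_along(members)) {
    a <- members[i]; ga <- owners[i]
    for (gb in owners[owners != ga]) {
      tab <- hits[[paste(ga, gb, sep = "|")]]
      if (is.null(tab)) next
      mine <- tab[tab$query_gene_id == a, , drop = FALSE]
      if (nrow(mine) == 0L) next
      partner_score <- mine$score[mine$subject_gene_id == partner_of[[gb]]]
      if (length(partner_score) == 0L) return(FALSE)
      if (any(mine$score > max(partner_score))) return(FALSE)
    }
    self_tab <- hits[[paste(ga, ga, sep = "|")]]
    if (!is.null(self_tab)) {
      self_hits <- self_tab[self_tab$query_gene_id == a &
                              self_tab$subject_gene_id != a, , drop = FALSE]
      if (nrow(self_hits) > 0L) {
        partner_scores <- vapply(owners[owners != ga], function(gb) {
          tab <- hits[[paste(ga, gb, sep = "|")]]
          s <- tab$score[tab$query_gene_id == a &
                           tab$subject_gene_id == partner_of[[gb]]]
          if (length(s) == 0L) -Inf else max(s)
        }, numeric(1))
        if (any(self_hits$score > min(partner_scores))) return(FALSE)
      }
    }
  }
  TRUE
}

#' Partition a reference genome into core and flexible compartments
#'
#' Reference genes belonging to any panortholog group are core; all other
#' protein-coding genes are flexible. `L_core` and `L_flex` are the summed
#' CDS lengths of the two compartments and always add up to the reference
#' total coding length.
#'
#' @param reference_annotation A `genome_annotation` for the reference genome.
#' @param panortholog_groups Group table from [build_panortholog_set()].
#' @return A `core_partition`: list with `genes` (tibble `gene_id`,
#'   `compartment`, `length_bp`), `core_gene_ids`, `flexible_gene_ids`,
#'   `L_core`, `L_flex`.
#' @export
classify_core_flexible <- function(reference_annotation, panortholog_groups) {
  ref_id <- reference_annotation$genome_id
  if (nrow(panortholog_groups) > 0L &&
      !ref_id %in% panortholog_groups$genome_id) {
    stop("reference genome ", ref_id, " absent from the panortholog groups")
  }
  core_ids <- panortholog_groups$gene_id[panortholog_groups$genome_id == ref_id]
  unknown <- setdiff(core_ids, reference_annotation$genes$gene_id)
  if (length(unknown) > 0L) {
    stop("panortholog gene(s) not in the reference annotation: ",
         paste(unknown, collapse = ", "))
  }
  genes <- tibble::tibble(
    gene_id = reference_annotation$genes$gene_id,
    compartment = ifelse(reference_annotation$genes$gene_id %in% core_ids,
                         "core", "flexible"),
    length_bp = nchar(reference_annotation$genes$nt_seq)
  )
  core_partition(genes)
}

#' Construct a core/flexible partition from a labelled gene table
#'
#' @param genes Tibble with columns `gene_id`, `compartment`
#'   (`"core"`/`"flexible"`), `length_bp`.
#' @return A `core_partition` object.
#' @export
core_partition <- function(genes) {
  stopifnot(all(c("gene_id", "compartment", "length_bp") %in% names(genes)),
            all(genes$compartment %in% c("core", "flexible")))
  structure(list(
    genes = tibble::as_tibble(genes),
    core_gene_ids = genes$gene_id[genes$compartment == "core"],
    flexible_gene_ids = genes$gene_id[genes$compartment == "flexible"],
    L_core = sum(genes$length_bp[genes$compartment == "core"]),
    L_flex = sum(genes$length_bp[genes$compartment == "flexible"])
  ), class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat("<core_partition> ", length(x$core_gene_ids), " core (",
      x$L_core, " bp), ", length(x$flexible_gene_ids), " flexible (",
      x$L_flex, " bp); core fraction ",
      sprintf("%.1f%%", 100 * core_fraction(x)), "\n", sep = "")
  invisible(x)
}

#' Core fraction of the coding genome
#'
#' @param L_core Either a `core_partition` or the summed core coding length
#'   in bp.
#' @param L_flex Summed flexible coding length in bp (ignored when `L_core`
#'   is a partition).
#' @return Fraction of coding sequence in the core compartment.
#' @export
core_fraction <- function(L_core, L_flex = NULL) {
  if (inherits(L_core, "core_partition")) {
    p <- L_core
    return(p$L_core / (p$L_core + p$L_flex))
  }
  L_core / (L_core + L_flex)
}

#' One-to-one interspecies ortholog calls
#'
#' Applies the reciprocal-best-hit rules to a two-genome comparison (for
#' example a species pair), returning the one-to-one ortholog pairs.
#'
#' @param proteins_a,proteins_b Named character vectors of proteins.
#' @param scorer A [scorer_config()].
#' @return Tibble with columns `gene_a`, `gene_b`.
#' @export
one_to_one_interspecies <- function(proteins_a, proteins_b,
                                    scorer = scorer_config()) {
  reciprocal_best_hits(score_all_pairs(proteins_a, proteins_b, scorer),
                       score_all_pairs(proteins_b, proteins_a, scorer))
}

#' Intersect two ortholog call sets
#'
#' Returns exactly the pairs present in both call sets, e.g. the consensus
#' between this pipeline's calls and an external orthology database.
#'
#' @param pairs_1,pairs_2 Tibbles with columns `gene_a`, `gene_b`.
#' @return Tibble of consensus pairs.
#' @export
intersect_ortholog_calls <- function(pairs_1, pairs_2) {
  dplyr::inner_join(pairs_1[, c("gene_a", "gene_b")],
                    pairs_2[, c("gene_a", "gene_b")],
                    by = c("gene_a", "gene_b"))
}
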