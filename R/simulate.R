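# stable sub-seed derivation, so each generated artifact draws from its own
# labelled substream of the run seed and partial regeneration is stable
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

sense_codons <- function(genetic_code_id = "11") {
  code <- genetic_code_table(genetic_code_id)
  names(code)[code != "*"]
}

#' Pangenome simulation configuration
#'
#' Defines a synthetic genome collection with known core/flexible structure:
#' core families present single-copy in every genome, flexible families
#' present per genome with a fixed probability (and guaranteed absent from
#' at least one), all members independently diverged from a family ancestor
#' (star topology) by per-codon substitution and occasional in-frame indels.
#'
#' @param n_genomes Number of genomes (default 5).
#' @param n_core,n_flexible Family counts (defaults 20 and 10).
#' @param flexible_presence_prob Per-genome presence probability of a
#'   flexible family (default 0.6).
#' @param gene_length_codons Inclusive bounds on ancestor length in codons,
#'   excluding the stop (default `c(40, 80)`).
#' @param per_site_substitution_prob Per-codon probability of substitution
#'   to a random different sense codon (default 0.02, keeping within-family
#'   amino-acid identity above ~0.9).
#' @param indel_prob Per-member probability of one in-frame indel (default
#'   0.05).
#' @param indel_length_codons Inclusive bounds on indel length in codons
#'   (default `c(1, 3)`).
#' @param force_absence Guarantee every flexible family absent from at least
#'   one genome (default TRUE); disabling it with presence probability 1
#'   makes every family behave as core.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `pangenome_sim_config`.
#' @export
pangenome_sim_config <- function(n_genomes = 5L, n_core = 20L,
                                 n_flexible = 10L,
                                 flexible_presence_prob = 0.6,
                                 gene_length_codons = c(40L, 80L),
                                 per_site_substitution_prob = 0.02,
                                 indel_prob = 0.05,
                                 indel_length_codons = c(1L, 3L),
                                 force_absence = TRUE,
                                 seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genomes >= 2L, n_core >= 0L, n_flexible >= 0L,
            flexible_presence_prob >= 0, flexible_presence_prob <= 1,
            per_site_substitution_prob >= 0, per_site_substitution_prob <= 1,
            indel_prob >= 0, indel_prob <= 1,
            length(gene_length_codons) == 2L,
            gene_length_codons[1] >= 10L,
            gene_length_codons[2] >= gene_length_codons[1])
  structure(as.list(environment()), class = "pangenome_sim_config")
}

random_cds <- function(n_codons, codons) {
  body <- sample(codons, n_codons - 1L, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

mutate_cds <- function(nt_seq, sub_prob, indel_prob, indel_bounds, codons) {
  cods <- codon_split(nt_seq)
  n <- length(cods)
  body_idx <- 2:(n - 1L)  # keep start and stop codons intact
  hit <- body_idx[stats::runif(length(body_idx)) < sub_prob]
  for (i in hit) {
    cods[i] <- sample(setdiff(codons, cods[i]), 1L)
  }
  if (stats::runif(1) < indel_prob && length(body_idx) > 2L * indel_bounds[2]) {
    k <- sample(indel_bounds[1]:indel_bounds[2], 1L)
    if (stats::runif(1) < 0.5) {
      at <- sample(body_idx[seq_len(length(body_idx) - k)], 1L)
      cods <- cods[-(at:(at + k - 1L))]
    } else {
      at <- sample(body_idx, 1L)
      cods <- append(cods, sample(codons, k, replace = TRUE), after = at)
    }
  }
  paste(cods, collapse = "")
}

#' Simulate a pangenome with known core/flexible truth
#'
#' @param config A [pangenome_sim_config()].
#' @return List with `genomes` (list of `genome_annotation`), `truth`
#'   (tibble `family_id`, `compartment`, `genome_id`, `gene_id`) and
#'   `config`. Fully reproducible per seed.
#' @export
simulate_pangenome <- function(config) {
  stopifnot(inherits(config, "pangenome_sim_config"))
  codons <- setdiff(sense_codons(), "ATG")
  with_local_seed(derive_seed(config$seed, "pangenome"), {
    genome_ids <- sprintf("g%02d", seq_len(config$n_genomes))
    fams <- c(
      if (config$n_core > 0) sprintf("core%03d", seq_len(config$n_core)),
      if (config$n_flexible > 0) sprintf("flex%03d", seq_len(config$n_flexible))
    )
    compartment <- rep(c("core", "flexible"),
                       c(config$n_core, config$n_flexible))
    presence <- matrix(TRUE, nrow = length(fams), ncol = config$n_genomes,
                       dimnames = list(fams, genome_ids))
    for (f in which(compartment == "flexible")) {
      pres <- stats::runif(config$n_genomes) < config$flexible_presence_prob
      if (!any(pres)) pres[sample(config$n_genomes, 1L)] <- TRUE
      if (all(pres) && config$force_absence) {
        pres[sample(config$n_genomes, 1L)] <- FALSE
      }
      presence[f, ] <- pres
    }
    ancestors <- stats::setNames(vapply(fams, function(f) {
      L <- sample(config$gene_length_codons[1]:config$gene_length_codons[2], 1L)
      random_cds(L, codons)
    }, character(1)), fams)

    truth <- list(); genomes <- list()
    for (gi in seq_along(genome_ids)) {
      gid <- genome_ids[gi]
      fam_here <- fams[presence[, gi]]
      rows <- list(); pos <- 1L
      for (f in fam_here) {
        nt <- mutate_cds(ancestors[[f]], config$per_site_substitution_prob,
                         config$indel_prob, config$indel_length_codons, codons)
        gene_id <- paste0(gid, "_", f)
        strand <- sample(c("+", "-"), 1L)
        rows[[f]] <- gene_model(gene_id, gid, "chr1", pos,
                                pos + nchar(nt) - 1L, strand, nt)
        truth[[gene_id]] <- tibble::tibble(
          family_id = f,
          compartment = compartment[match(f, fams)],
          genome_id = gid, gene_id = gene_id
        )
        pos <- pos + nchar(nt) + 100L
      }
      genomes[[gid]] <- genome_annotation(gid, dplyr::bind_rows(rows))
    }
    list(genomes = genomes, truth = dplyr::bind_rows(truth), config = config)
  })
}

#' Mutation table simulation configuration
#'
#' Emulates the structure of an evolution experiment's clone-sequencing
#' mutation table: six nonmutator and six mutator populations, nonsynonymous
#' events placed on genes with a per-bp rate elevated by the enrichment
#' factor `r` in the core compartment, and synonymous events placed
#' length-proportionally with no enrichment. Default event totals mirror a
#' 50,000-generation clone collection (174 + 20 nonmutator nonsynonymous +
#' synonymous point mutations; 4775 + 1698 mutator) and the default planted
#' enrichment is r = 2.5.
#'
#' @param n_nonmutator_events,n_mutator_events Total events per mutator
#'   context (defaults 194 and 6473).
#' @param syn_fraction_nonmutator,syn_fraction_mutator Fraction of events
#'   that are synonymous in each context (defaults 20/194 and 1698/6473).
#' @param core_enrichment_factor Planted per-bp nonsynonymous rate ratio,
#'   core over flexible (default 2.5; must be > 0).
#' @param knockout_event_prob Named numeric vector: probability that a
#'   nonsynonymous-slot event is instead a `small_indel`, `is_insertion` or
#'   `large_deletion` (defaults 0.04, 0.02, 0.01).
#' @param duplicate_obs_prob Probability an event is observed in two clones
#'   of its population (default 0.1).
#' @param seed Mandatory integer seed.
#' @return A validated list of class `mutation_sim_config`.
#' @export
mutation_sim_config <- function(n_nonmutator_events = 194L,
                                n_mutator_events = 6473L,
                                syn_fraction_nonmutator = 20 / 194,
                                syn_fraction_mutator = 1698 / 6473,
                                core_enrichment_factor = 2.5,
                                knockout_event_prob = c(small_indel = 0.04,
                                                        is_insertion = 0.02,
                                                        large_deletion = 0.01),
                                duplicate_obs_prob = 0.1,
                                seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_nonmutator_events >= 0L, n_mutator_events >= 0L,
            core_enrichment_factor > 0,
            syn_fraction_nonmutator >= 0, syn_fraction_nonmutator <= 1,
            syn_fraction_mutator >= 0, syn_fraction_mutator <= 1,
            all(knockout_event_prob >= 0), sum(knockout_event_prob) < 1)
  structure(as.list(environment()), class = "mutation_sim_config")
}

NONMUTATOR_POPULATIONS <- c("Ara-5", "Ara-6", "Ara+1", "Ara+2", "Ara+4", "Ara+5")
MUTATOR_POPULATIONS <- c("Ara-1", "Ara-2", "Ara-3", "Ara-4", "Ara+3", "Ara+6")

# codon_to candidates of a codon matching a target class ("synonymous" or
# nonsynonymous-including-nonsense); precomputed once per genetic code
codon_targets <- local({
  cache <- new.env(parent = emptyenv())
  build <- function(genetic_code_id) {
    nts <- c("A", "C", "G", "T")
    all_codons <- names(genetic_code_table(genetic_code_id))
    tab <- list()
    for (codon in all_codons) {
      chars <- strsplit(codon, "", fixed = TRUE)[[1]]
      syn <- character(0); nonsyn <- character(0)
      for (pos in 1:3) for (nt in setdiff(nts, chars[pos])) {
        mut <- chars; mut[pos] <- nt
        cand <- paste(mut, collapse = "")
        if (classify_snp(codon, cand, genetic_code_id) == "synonymous") {
          syn <- c(syn, cand)
        } else {
          nonsyn <- c(nonsyn, cand)
        }
      }
      tab[[codon]] <- list(syn = syn, nonsyn = nonsyn)
    }
    tab
  }
  function(codon, want_syn, genetic_code_id = "11") {
    key <- as.character(genetic_code_id)
    if (is.null(cache[[key]])) cache[[key]] <- build(key)
    cache[[key]][[codon]][[if (want_syn) "syn" else "nonsyn"]]
  }
})

#' Simulate a mutation table with a planted core enrichment
#'
#' @param config A [mutation_sim_config()].
#' @param partition A `core_partition` of the reference genome.
#' @param annotation The reference `genome_annotation` (provides the codons
#'   that make generated `codon_from`/`codon_to` pairs self-consistent with
#'   their labelled class).
#' @return List with `mutations` (tibble in the standard table schema plus
#'   `indel_length`) and `truth` (planted r, per-compartment realized SNP
#'   counts by context and class).
#' @export
simulate_mutation_table <- function(config, partition, annotation) {
  stopifnot(inherits(config, "mutation_sim_config"),
            inherits(partition, "core_partition"))
  genes <- dplyr::inner_join(partition$genes,
                             annotation$genes[, c("gene_id", "start", "end",
                                                  "strand", "nt_seq")],
                             by = "gene_id")
  if (nrow(genes) == 0L) stop("partition and annotation share no genes")
  if (partition$L_core + partition$L_flex == 0) stop("partition missing lengths")
  r <- config$core_enrichment_factor
  w_nonsyn <- genes$length_bp * ifelse(genes$compartment == "core", r, 1)
  w_syn <- genes$length_bp

  draw_events <- function(context, n_events, syn_fraction) {
    if (n_events == 0L) return(NULL)
    n_syn <- stats::rbinom(1L, n_events, syn_fraction)
    n_nonsyn_slot <- n_events - n_syn
    cat_probs <- c(config$knockout_event_prob,
                   snp = 1 - sum(config$knockout_event_prob))
    cats <- sample(names(cat_probs), n_nonsyn_slot, replace = TRUE,
                   prob = cat_probs)
    pops <- if (context == "nonmutator") NONMUTATOR_POPULATIONS else
      MUTATOR_POPULATIONS
    make <- function(n, want_syn, categories) {
      if (n == 0L) return(NULL)
      weights <- if (want_syn) w_syn else w_nonsyn
      gi <- sample(nrow(genes), n, replace = TRUE, prob = weights)
      position <- integer(n)
      codon_from <- rep(NA_character_, n); codon_to <- rep(NA_character_, n)
      residue_index <- rep(NA_integer_, n); indel_length <- rep(NA_integer_, n)
      for (k in seq_len(n)) {
        g_start <- genes$start[gi[k]]; g_end <- genes$end[gi[k]]
        g_nt <- genes$nt_seq[gi[k]]; g_strand <- genes$strand[gi[k]]
        if (categories[k] == "snp") {
          n_codons <- nchar(g_nt) %/% 3L - 1L  # exclude stop
          repeat {
            ci <- sample(2:n_codons, 1L)
            cf <- substr(g_nt, 3L * ci - 2L, 3L * ci)
            cands <- codon_targets(cf, want_syn)
            if (length(cands) > 0L) break
          }
          codon_from[k] <- cf
          codon_to[k] <- if (length(cands) == 1L) cands else sample(cands, 1L)
          residue_index[k] <- ci
          offset <- 3L * (ci - 1L) + sample(0:2, 1L)
          position[k] <- if (g_strand == "+") g_start + offset else
            g_end - offset
        } else {
          indel_length[k] <- switch(categories[k],
            small_indel = sample(c(1L, 2L, 4L, 5L, 7L, 8L), 1L),
            is_insertion = 1329L,
            large_deletion = sample(50:5000, 1L)
          )
          position[k] <- sample(g_start:g_end, 1L)
        }
      }
      tibble::tibble(
        gene_id = genes$gene_id[gi], position = position,
        category = categories, codon_from = codon_from, codon_to = codon_to,
        residue_index = residue_index, indel_length = indel_length,
        snp_class_truth = ifelse(categories == "snp",
                                 if (want_syn) "synonymous" else "nonsynonymous",
                                 NA_character_),
        compartment_truth = genes$compartment[gi]
      )
    }
    ev <- dplyr::bind_rows(
      make(n_syn, TRUE, rep("snp", n_syn)),
      make(n_nonsyn_slot, FALSE, cats)
    )
    ev$population <- sample(pops, nrow(ev), replace = TRUE)
    ev$mutator_context <- context
    ev
  }

  with_local_seed(derive_seed(config$seed, "mutations"), {
    ev <- dplyr::bind_rows(
      draw_events("nonmutator", config$n_nonmutator_events,
                  config$syn_fraction_nonmutator),
      draw_events("mutator", config$n_mutator_events,
                  config$syn_fraction_mutator)
    )
    ev$generation <- 50000L
    ev$independent_event_id <- sprintf("ev%06d", seq_len(nrow(ev)))
    ev$on_line_of_descent <- stats::runif(nrow(ev)) < 0.5
    ev$clone_id <- paste0(ev$population, "_c1")
    dup <- which(stats::runif(nrow(ev)) < config$duplicate_obs_prob)
    if (length(dup) > 0L) {
      second <- ev[dup, ]
      second$clone_id <- paste0(second$population, "_c2")
      ev <- dplyr::bind_rows(ev, second)
    }
    mutations <- ev[, c("population", "generation", "clone_id", "gene_id",
                        "position", "category", "codon_from", "codon_to",
                        "residue_index", "mutator_context",
                        "on_line_of_descent", "independent_event_id",
                        "indel_length", "snp_class_truth",
                        "compartment_truth")]
    events <- ev[!duplicated(ev$independent_event_id), ]
    snp_counts <- events |>
      dplyr::filter(.data$category == "snp") |>
      dplyr::count(.data$mutator_context, .data$snp_class_truth,
                   .data$compartment_truth)
    list(
      mutations = mutations,
      truth = list(core_enrichment_factor = r,
                   p_core_nonsyn = r * partition$L_core /
                     (r * partition$L_core + partition$L_flex),
                   snp_event_counts = snp_counts)
    )
  })
}

#' Essentiality-screen simulation configuration
#'
#' Generates per-gene integer essentiality scores on the +3 (essential) to
#' -4 (dispensable) scale of a single-gene knockout screen, drawn from
#' compartment-specific distributions so the planted core-vs-flexible
#' difference is recoverable downstream.
#'
#' @param core_score_probs,flex_score_probs Probability weights over the
#'   scores -4, -3, ..., +3 (in that order). The defaults put more mass on
#'   positive scores for core genes.
#' @param seed Mandatory integer seed.
#' @return A validated list of class `essentiality_sim_config`.
#' @export
essentiality_sim_config <- function(
    core_score_probs = c(0.05, 0.07, 0.08, 0.12, 0.14, 0.16, 0.18, 0.20),
    flex_score_probs = c(0.20, 0.18, 0.16, 0.14, 0.12, 0.08, 0.07, 0.05),
    seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(core_score_probs) == 8L, length(flex_score_probs) == 8L,
            all(core_score_probs >= 0), all(flex_score_probs >= 0),
            sum(core_score_probs) > 0, sum(flex_score_probs) > 0)
  structure(as.list(environment()), class = "essentiality_sim_config")
}

ESSENTIALITY_SCORES <- -4:3

#' Simulate an essentiality score table
#'
#' @param config An [essentiality_sim_config()].
#' @param partition A `core_partition` supplying gene ids and compartments.
#' @return Tibble with `gene_id`, `compartment`, `essentiality_score`
#'   (integers in -4..+3).
#' @export
simulate_essentiality_table <- function(config, partition) {
  stopifnot(inherits(config, "essentiality_sim_config"),
            inherits(partition, "core_partition"))
  g <- partition$genes
  with_local_seed(derive_seed(config$seed, "essentiality"), {
    is_core <- g$compartment == "core"
    score <- integer(nrow(g))
    score[is_core] <- sample(ESSENTIALITY_SCORES, sum(is_core),
                             replace = TRUE, prob = config$core_score_probs)
    score[!is_core] <- sample(ESSENTIALITY_SCORES, sum(!is_core),
                              replace = TRUE, prob = config$flex_score_probs)
    tibble::tibble(gene_id = g$gene_id, compartment = g$compartment,
                   essentiality_score = score)
  })
}

#' Simulate a toy multi-chain structure with planted contact distances
#'
#' Builds `n_chains` short protein chains in PDB text: chain A lies along
#' the x axis at the origin and each further chain is a parallel copy
#' displaced perpendicular to it, so the minimum inter-atom distance between
#' chain A and chain k equals `planted_min_distances[k-1]` exactly. Chains
#' are fanned out in distinct directions.
#'
#' @param n_chains Number of chains (>= 2).
#' @param planted_min_distances Positive distances in angstrom, length
#'   `n_chains - 1`.
#' @param seed Accepted for interface uniformity; the geometry is
#'   deterministic.
#' @return Character scalar of PDB text.
#' @export
simulate_toy_structure <- function(n_chains, planted_min_distances,
                                   seed = NULL) {
  stopifnot(n_chains >= 2L, length(planted_min_distances) == n_chains - 1L)
  if (any(planted_min_distances <= 0)) {
    stop("infeasible geometry: planted distances must be positive")
  }
  chain_ids <- LETTERS[seq_len(n_chains)]
  atom_x <- c(0, 1.5, 3.0)
  atom_names <- c(" N  ", " CA ", " C  ")
  lines <- character(0); serial <- 0L
  angles <- 2 * pi * (seq_len(n_chains - 1L) - 1L) / max(1L, n_chains - 1L)
  for (k in seq_len(n_chains)) {
    if (k == 1L) {
      oy <- 0; oz <- 0
    } else {
      d <- planted_min_distances[k - 1L]
      oy <- d * cos(angles[k - 1L]); oz <- d * sin(angles[k - 1L])
    }
    for (j in 1:3) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, atom_names[j], " ", "GLY", chain_ids[k], 1L, " ",
        atom_x[j], oy, oz, 1.0, 0.0, substr(trimws(atom_names[j]), 1, 1)
      ))
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                              "GLY", chain_ids[k], 1L))
  }
  paste(c(lines, "END"), collapse = "\n")
}
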