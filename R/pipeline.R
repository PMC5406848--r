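run_config_defaults <- function() {
  list(
    outdir = "coreflex_out",
    reference_genome = NULL,       # default: first simulated genome
    genetic_code_id = "11",
    rho = 3.22,
    min_identity = 0.5,
    min_coverage = 0.5,
    near_terminal_codons = 5L,
    contact_threshold = 8.0,
    n_boot = 1000L,
    n_genomes = 5L,
    n_core = 20L,
    n_flexible = 10L,
    flexible_presence_prob = 0.6,
    per_site_substitution_prob = 0.02,
    indel_prob = 0.05,
    n_nonmutator_events = 194L,
    n_mutator_events = 6473L,
    core_enrichment_factor = 2.5,
    n_structure_chains = 2L,
    structure_distances = c(5.0)
  )
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list, fills defaults (e.g. site
#' ratio rho = 3.22, contact threshold 8 angstrom, identity/coverage 0.5)
#' and reports *all* violations at once, not just the first. A seed is
#' mandatory; unknown keys are errors.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A fully-resolved list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- run_config_defaults()
  problems <- character(0)
  unknown <- setdiff(names(config), c(names(defaults), "seed"))
  if (length(unknown) > 0L) {
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  if (is.null(config$seed)) {
    problems <- c(problems, "seed is required")
  } else if (!is.numeric(config$seed) || config$seed != round(config$seed)) {
    problems <- c(problems, "seed must be an integer")
  }
  merged <- utils::modifyList(defaults, config)
  num_checks <- list(
    rho = c(0, Inf), min_identity = c(0, 1), min_coverage = c(0, 1),
    contact_threshold = c(0, Inf), flexible_presence_prob = c(0, 1),
    per_site_substitution_prob = c(0, 1), core_enrichment_factor = c(0, Inf)
  )
  for (key in names(num_checks)) {
    v <- merged[[key]]
    if (!is.numeric(v) || v < num_checks[[key]][1] || v > num_checks[[key]][2]) {
      problems <- c(problems, paste0(key, " out of range [",
                                     num_checks[[key]][1], ", ",
                                     num_checks[[key]][2], "]"))
    }
  }
  if (length(problems) > 0L) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  merged$seed <- as.integer(merged$seed)
  structure(merged, class = c("run_config", "list"))
}

write_tsv_na <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage end to end on data generated from the validated
#' configuration: pangenome simulation, ortholog search and core/flexible
#' partition, family alignment and diversity, mutation simulation and
#' annotation, compartment enrichment and dN/dS, G scores and their
#' relationship to diversity and divergence, site-partitioned diversity at
#' mutated residues, the essentiality/knockout cross-tabulation, and
#' structure contact distances. Emits one tab-separated table per analysis
#' under `outdir` and is deterministic given the configuration.
#'
#' @param config A `run_config` from [validate_config()] (or a list/path
#'   accepted by it).
#' @return A `run_report`: list with `tables` (named tibbles), `files`
#'   (tibble of emitted paths with md5 checksums and row counts),
#'   `parameters` (the resolved configuration) and `partition`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sim <- stage("simulate_pangenome", {
    simulate_pangenome(pangenome_sim_config(
      n_genomes = config$n_genomes, n_core = config$n_core,
      n_flexible = config$n_flexible,
      flexible_presence_prob = config$flexible_presence_prob,
      per_site_substitution_prob = config$per_site_substitution_prob,
      indel_prob = config$indel_prob,
      seed = derive_seed(config$seed, "pangenome_stage")
    ))
  })
  genomes <- sim$genomes
  ref_id <- config$reference_genome %||% names(genomes)[1]
  if (!ref_id %in% names(genomes)) {
    stop("stage 'pangenome' failed: reference genome ", ref_id, " not present")
  }

  partition <- stage("pangenome", {
    scorer <- scorer_config(min_identity = config$min_identity,
                            min_coverage = config$min_coverage)
    prots <- lapply(genomes, proteome)
    ids <- names(genomes)
    hits <- list()
    for (qa in ids) for (qb in ids) {
      hits[[paste(qa, qb, sep = "|")]] <-
        score_all_pairs(prots[[qa]], prots[[qb]], scorer)
    }
    rbh_sets <- list()
    for (pair in utils::combn(sort(ids), 2L, simplify = FALSE)) {
      key <- paste(pair, collapse = "|")
      rbh_sets[[key]] <- reciprocal_best_hits(
        hits[[paste(pair[1], pair[2], sep = "|")]],
        hits[[paste(pair[2], pair[1], sep = "|")]]
      )
    }
    groups <- build_panortholog_set(genomes, rbh_sets, hits)
    list(groups = groups,
         partition = classify_core_flexible(genomes[[ref_id]], groups))
  })
  groups <- partition$groups
  partition <- partition$partition

  diversity <- stage("diversity", {
    fam_ids <- unique(groups$family_id)
    all_prots <- unlist(unname(lapply(genomes, proteome)))
    alns <- list(); out <- vector("list", length(fam_ids))
    for (i in seq_along(fam_ids)) {
      fam <- groups[groups$family_id == fam_ids[i], ]
      ref_gene <- fam$gene_id[fam$genome_id == ref_id]
      seqs <- stats::setNames(all_prots[fam$gene_id], fam$genome_id)
      aln <- align_family(seqs, family_id = ref_gene)
      alns[[ref_gene]] <- aln
      out[[i]] <- pairwise_aa_diversity(aln)
    }
    list(table = dplyr::bind_rows(out), alignments = alns)
  })
  alignments <- diversity$alignments
  diversity <- dplyr::select(diversity$table, -"per_column_diff_counts")

  divergence <- stage("divergence", {
    other_id <- setdiff(names(genomes), ref_id)[1]
    out <- lapply(names(alignments), function(ref_gene) {
      aln <- alignments[[ref_gene]]
      if (!all(c(ref_id, other_id) %in% names(aln$rows))) return(NULL)
      # realign the pair directly rather than reusing (possibly gappy)
      # family columns
      pairwise_divergence(align_family(
        stats::setNames(gsub("-", "", aln$rows[c(ref_id, other_id)],
                             fixed = TRUE), c(ref_id, other_id)),
        family_id = ref_gene))
    })
    dplyr::bind_rows(out)
  })

  mut_sim <- stage("simulate_mutations", {
    simulate_mutation_table(
      mutation_sim_config(
        n_nonmutator_events = config$n_nonmutator_events,
        n_mutator_events = config$n_mutator_events,
        core_enrichment_factor = config$core_enrichment_factor,
        seed = derive_seed(config$seed, "mutation_stage")
      ),
      partition, genomes[[ref_id]]
    )
  })
  mutations <- stage("mutation_annotation", {
    annotate_mutations(mut_sim$mutations, genomes[[ref_id]],
                       genetic_code_id = config$genetic_code_id,
                       near_terminal_codons = config$near_terminal_codons)
  })

  enrichment <- stage("enrichment", {
    mutation_events <- independent_event_collapse(mutations)
    rows <- list()
    for (ctx in c("nonmutator", "mutator")) {
      for (cls in c("nonsynonymous", "synonymous")) {
        n <- tabulate_compartment_counts(mutation_events, partition,
                                         mutator_context = ctx,
                                         snp_class = cls)
        rows[[paste(ctx, cls)]] <- dplyr::bind_cols(
          tibble::tibble(mutator_context = ctx, snp_class = cls),
          enrichment_test(n[["core"]], n[["flexible"]],
                          partition$L_core, partition$L_flex)
        )
      }
    }
    dplyr::bind_rows(rows)
  })

  dnds <- stage("dnds", {
    mutation_events <- independent_event_collapse(mutations)
    rows <- lapply(c("nonmutator", "mutator"), function(ctx) {
      m <- mutation_events[mutation_events$mutator_context == ctx &
                             !is.na(mutation_events$snp_class), ]
      comp <- stats::setNames(partition$genes$compartment,
                              partition$genes$gene_id)[m$gene_id]
      dplyr::bind_rows(lapply(c("core", "flexible"), function(cp) {
        nonsyn <- sum(comp == cp & is_nonsynonymous(m$snp_class))
        syn <- sum(comp == cp & m$snp_class == "synonymous")
        if (syn == 0L) return(NULL)
        dplyr::bind_cols(
          tibble::tibble(mutator_context = ctx, compartment = cp),
          dnds_ratio(nonsyn, syn, config$rho)
        )
      }))
    })
    dplyr::bind_rows(rows)
  })

  gscore_tab <- stage("gscore", {
    events <- independent_event_collapse(mutations)
    hits <- events[events$mutator_context == "nonmutator" &
                     !is.na(events$snp_class) &
                     is_nonsynonymous(events$snp_class), ]
    counts <- table(hits$gene_id)
    g <- partition$genes
    gscores(tibble::tibble(
      gene_id = g$gene_id, L = g$length_bp,
      O = as.integer(counts[g$gene_id]) |> (\(x) ifelse(is.na(x), 0L, x))()
    ))
  })

  gscore_vs_diversity <- stage("gscore_vs_diversity", {
    tab <- dplyr::inner_join(gscore_tab, diversity, by = "gene_id")
    stats_out <- list()
    if (nrow(tab) >= 3L && length(unique(tab$G)) > 1L &&
        length(unique(tab$pi_aa)) > 1L) {
      stats_out$spearman <- spearman_correlation(tab$G, tab$pi_aa)
      pos <- tab$pi_aa[tab$G > 0]; zero <- tab$pi_aa[tab$G == 0]
      if (length(pos) > 0L && length(zero) > 0L) {
        stats_out$mann_whitney <- mann_whitney(pos, zero)
        stats_out$ci_positive <- tibble::tibble(
          method = "bootstrap_median_ci_positive_G",
          statistic = bootstrap_median_ci(
            pos, n_boot = config$n_boot,
            seed = derive_seed(config$seed, "ci_pos"))$median,
          p_value = NA_real_, sidedness = NA_character_,
          n1 = length(pos), n2 = NA_integer_)
      }
    }
    list(table = tab, tests = dplyr::bind_rows(stats_out))
  })

  gscore_vs_divergence <- stage("gscore_vs_divergence", {
    tab <- dplyr::inner_join(gscore_tab, divergence, by = "gene_id")
    tests <- if (nrow(tab) >= 3L && length(unique(tab$G)) > 1L &&
                 length(unique(tab$d)) > 1L) {
      spearman_correlation(tab$G, tab$d)
    } else {
      NULL
    }
    list(table = tab, tests = tests)
  })

  site_partition <- stage("site_partition", {
    snp_hits <- mutations[mutations$mutator_context == "nonmutator" &
                            !is.na(mutations$snp_class) &
                            is_nonsynonymous(mutations$snp_class) &
                            mutations$gene_id %in% names(alignments), ]
    out <- lapply(split(snp_hits, snp_hits$gene_id), function(h) {
      aln <- alignments[[h$gene_id[1]]]
      n_res <- nchar(gsub("-", "", aln$rows[[ref_id]], fixed = TRUE))
      idx <- unique(h$residue_index[h$residue_index <= n_res])
      if (length(idx) == 0L) return(NULL)
      cols <- map_residue_to_column(aln, ref_id, idx)
      partition_site_diversity(aln, cols)
    })
    tab <- dplyr::bind_rows(out)
    test <- NULL
    if (nrow(tab) >= 2L && any(tab$pi_target != tab$pi_rest, na.rm = TRUE)) {
      ok <- stats::complete.cases(tab[, c("pi_target", "pi_rest")])
      test <- wilcoxon_signed_rank(tab$pi_target[ok], tab$pi_rest[ok])
    }
    list(table = tab, test = test)
  })

  knockout_essentiality <- stage("knockout_essentiality", {
    ess <- simulate_essentiality_table(
      essentiality_sim_config(seed = derive_seed(config$seed, "ess_stage")),
      partition
    )
    core_scores <- ess$essentiality_score[ess$compartment == "core"]
    flex_scores <- ess$essentiality_score[ess$compartment == "flexible"]
    welch <- if (length(core_scores) >= 2L && length(flex_scores) >= 2L) {
      welch_t(core_scores, flex_scores, sidedness = "greater")
    } else {
      NULL
    }
    events <- independent_event_collapse(mutations)
    nonsyn_events <- events[events$mutator_context == "nonmutator" &
                              !is.na(events$snp_class) &
                              is_nonsynonymous(events$snp_class), ]
    multi_hit <- names(which(table(nonsyn_events$gene_id) >= 2L))
    ko_genes <- unique(events$gene_id[
      events$mutator_context == "nonmutator" &
        !is.na(events$is_potential_knockout) & events$is_potential_knockout])
    tab <- ess[ess$gene_id %in% multi_hit & ess$essentiality_score != 0L, ]
    fisher <- NULL
    if (nrow(tab) >= 2L) {
      m <- matrix(c(
        sum(tab$essentiality_score > 0 & tab$gene_id %in% ko_genes),
        sum(tab$essentiality_score > 0 & !tab$gene_id %in% ko_genes),
        sum(tab$essentiality_score < 0 & tab$gene_id %in% ko_genes),
        sum(tab$essentiality_score < 0 & !tab$gene_id %in% ko_genes)
      ), nrow = 2L, byrow = TRUE)
      fisher <- fisher_exact_one_tailed(m, direction = "less")
    }
    list(essentiality = ess, welch = welch, fisher = fisher,
         multi_hit_genes = multi_hit, knockout_genes = ko_genes)
  })

  contacts <- stage("contacts", {
    pdb_text <- simulate_toy_structure(
      config$n_structure_chains,
      config$structure_distances,
      seed = derive_seed(config$seed, "structure_stage")
    )
    model <- parse_structure(pdb_text, structure_id = "toy")
    dplyr::bind_rows(lapply(names(model$chain_types), function(ch) {
      if (ch == "A") return(NULL)
      res <- min_distance_to_partners(model, ch, 1L,
                                      threshold = config$contact_threshold)
      res
    }))
  })

  tables <- list(
    partition = partition$genes,
    ortholog_groups = groups,
    diversity = diversity,
    divergence = divergence,
    mutations = mutations,
    enrichment_table = enrichment,
    dnds_table = dnds,
    gscores = gscore_tab,
    gscore_vs_diversity = gscore_vs_diversity$table,
    gscore_vs_diversity_tests = gscore_vs_diversity$tests,
    gscore_vs_divergence = gscore_vs_divergence$table,
    site_partition = site_partition$table,
    knockout_essentiality = knockout_essentiality$essentiality,
    contacts = contacts
  )
  tables <- tables[!vapply(tables, is.null, logical(1))]
  files <- lapply(names(tables), function(nm) {
    path <- write_tsv_na(tables[[nm]], file.path(config$outdir,
                                                 paste0(nm, ".tsv")))
    tibble::tibble(table = nm, path = path, n_rows = nrow(tables[[nm]]),
                   md5 = unname(tools::md5sum(path)))
  })
  files <- dplyr::bind_rows(files)
  log_path <- file.path(config$outdir, "run_log.txt")
  writeLines(c(
    "coreflex pipeline run",
    paste0("seed: ", config$seed),
    paste0("reference_genome: ", ref_id),
    paste0("rho: ", config$rho),
    paste0("genetic_code_id: ", config$genetic_code_id),
    paste0("min_identity: ", config$min_identity),
    paste0("min_coverage: ", config$min_coverage),
    paste0("contact_threshold: ", config$contact_threshold),
    paste0("n_boot: ", config$n_boot),
    paste0("core_enrichment_factor (planted): ",
           config$core_enrichment_factor),
    "emitted files:",
    paste0("  ", files$path, "  md5=", files$md5)
  ), log_path)

  structure(list(
    tables = tables, files = files, parameters = unclass(config),
    partition = partition,
    tests = list(
      gscore_vs_diversity = gscore_vs_diversity$tests,
      gscore_vs_divergence = gscore_vs_divergence$tests,
      site_partition = site_partition$test,
      essentiality_welch = knockout_essentiality$welch,
      knockout_fisher = knockout_essentiality$fisher
    ),
    truth = list(pangenome = sim$truth, mutations = mut_sim$truth),
    log_path = log_path
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", nrow(x$files), " tables written\n", sep = "")
  print(x$files)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
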