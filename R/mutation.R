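#' Classify a single-nucleotide codon change
#'
#' A change is synonymous iff both codons encode the same amino acid;
#' a change creating a stop codon is classed `"nonsense"`, which all tallies
#' in this package count as nonsynonymous; everything else is
#' `"nonsynonymous"`. Vectorized over codon pairs.
#'
#' @param codon_from,codon_to Three-letter nucleotide codons, differing at
#'   one or more positions.
#' @param genetic_code_id NCBI translation table identifier (default
#'   bacterial, `"11"`).
#' @return Character vector with values `"synonymous"`, `"nonsynonymous"`,
#'   `"nonsense"`.
#' @export
classify_snp <- function(codon_from, codon_to, genetic_code_id = "11") {
  codon_from <- toupper(codon_from); codon_to <- toupper(codon_to)
  ok <- grepl("^[ACGT]{3}$", codon_from) & grepl("^[ACGT]{3}$", codon_to)
  if (!all(ok)) {
    stop("invalid codon(s): ",
         paste(unique(c(codon_from[!ok], codon_to[!ok])), collapse = ", "))
  }
  if (any(codon_from == codon_to)) {
    stop("codon_from and codon_to must differ")
  }
  code <- genetic_code_table(genetic_code_id)
  aa_from <- unname(code[codon_from])
  aa_to <- unname(code[codon_to])
  dplyr::case_when(
    aa_to == "*" & aa_from != "*" ~ "nonsense",
    aa_from == aa_to ~ "synonymous",
    TRUE ~ "nonsynonymous"
  )
}

#' Does a SNP class count as nonsynonymous?
#'
#' Nonsense changes are reported distinctly by [classify_snp()] but count as
#' nonsynonymous in all tallies.
#'
#' @param snp_class Character vector of classes.
#' @return Logical vector.
#' @export
is_nonsynonymous <- function(snp_class) {
  snp_class %in% c("nonsynonymous", "nonsense")
}

# per-codon (syn, nonsyn) fractional site counts, cached per genetic code
codon_site_table <- local({
  cache <- new.env(parent = emptyenv())
  function(genetic_code_id = "11") {
    key <- as.character(genetic_code_id)
    if (!is.null(cache[[key]])) return(cache[[key]])
    code <- genetic_code_table(genetic_code_id)
    nts <- c("A", "C", "G", "T")
    sense <- names(code)[code != "*"]
    tab <- t(vapply(sense, function(codon) {
      chars <- strsplit(codon, "", fixed = TRUE)[[1]]
      syn <- 0
      for (pos in 1:3) for (nt in setdiff(nts, chars[pos])) {
        mut <- chars; mut[pos] <- nt
        mut_codon <- paste(mut, collapse = "")
        # stop-creating changes count as nonsynonymous
        if (code[[mut_codon]] != "*" && code[[mut_codon]] == code[[codon]]) {
          syn <- syn + 1
        }
      }
      c(syn_sites = syn / 3, nonsyn_sites = (9 - syn) / 3)
    }, numeric(2)))
    cache[[key]] <- tab
    tab
  }
})

#' Count synonymous and nonsynonymous sites in a CDS
#'
#' Equal-weight (Nei-Gojobori style) site counting: each of the nine
#' possible single-nucleotide changes of a codon contributes 1/3 of a site,
#' classed synonymous iff it preserves the amino acid; changes creating a
#' stop count as nonsynonymous. No transition/transversion weighting. A
#' single trailing stop codon is excluded; an internal stop is an error.
#' `syn_sites + nonsyn_sites` always equals 3 x the number of (non-stop)
#' codons.
#'
#' @param cds_nt_seq Coding-strand CDS (length divisible by 3).
#' @param genetic_code_id NCBI translation table identifier.
#' @return Named numeric vector `c(nonsyn_sites=, syn_sites=)`.
#' @export
count_syn_nonsyn_sites <- function(cds_nt_seq, genetic_code_id = "11") {
  cds_nt_seq <- toupper(cds_nt_seq)
  if (nchar(cds_nt_seq) %% 3L != 0L) {
    stop("CDS length not divisible by 3 (trailing partial codon)")
  }
  code <- genetic_code_table(genetic_code_id)
  codons <- codon_split(cds_nt_seq)
  aa <- code[codons]
  if (anyNA(aa)) stop("invalid codon(s) in CDS")
  n <- length(codons)
  if (aa[n] == "*") { codons <- codons[-n]; aa <- aa[-n] }
  if (any(aa == "*")) {
    stop("internal stop codon at codon position ",
         paste(which(aa == "*"), collapse = ", "))
  }
  tab <- codon_site_table(genetic_code_id)
  counts <- tab[codons, , drop = FALSE]
  c(nonsyn_sites = sum(counts[, "nonsyn_sites"]),
    syn_sites = sum(counts[, "syn_sites"]))
}

#' Genome-wide nonsynonymous-to-synonymous site ratio
#'
#' The ratio rho = sum(nonsynonymous sites) / sum(synonymous sites) over a
#' set of coding sequences, used to normalize count-based dN/dS.
#'
#' @param cds_seqs Character vector of CDS nucleotide sequences.
#' @param genetic_code_id NCBI translation table identifier.
#' @return A single positive number.
#' @export
site_ratio <- function(cds_seqs, genetic_code_id = "11") {
  totals <- rowSums(vapply(cds_seqs, count_syn_nonsyn_sites,
                           numeric(2), genetic_code_id = genetic_code_id))
  unname(totals["nonsyn_sites"] / totals["syn_sites"])
}

#' Flag a mutation as a potential gene knockout
#'
#' Potential knockouts are the event classes likely to abolish gene function
#' rather than fine-tune it: small indels whose length is not a multiple of
#' 3 (reading-frame disruption), insertion-sequence (IS) element insertions,
#' and large deletions overlapping the gene. Point mutations are never
#' flagged. Events within a short tail of the stop codon are additionally
#' marked `near_terminal`, since a frameshift in, say, the penultimate codon
#' may leave the product functional.
#'
#' @param record One mutation record (list or one-row data frame) with at
#'   least `category`, `position`, and for indels `indel_length`.
#' @param gene_model One-row gene model (needs `gene_id`, `start`, `end`,
#'   `strand`).
#' @param near_terminal_codons Tail width in codons (default 5).
#' @return Tibble with `gene_id`, `is_potential_knockout`, `reason`,
#'   `near_terminal`, `codons_to_stop`.
#' @export
flag_potential_knockout <- function(record, gene_model,
                                    near_terminal_codons = 5L) {
  category <- record$category
  pos <- record$position
  g <- gene_model
  if (category == "large_deletion") {
    del_end <- pos + record$indel_length - 1L
    if (del_end < g$start || pos > g$end) {
      stop("large deletion [", pos, ", ", del_end,
           "] does not overlap gene ", g$gene_id, " [", g$start, ", ", g$end, "]")
    }
  }
  reason <- "none"
  if (category == "small_indel" && !is.null(record$indel_length) &&
      !is.na(record$indel_length) && record$indel_length %% 3L != 0L) {
    reason <- "small_indel"
  } else if (category == "is_insertion") {
    reason <- "is_insertion"
  } else if (category == "large_deletion") {
    reason <- "large_deletion"
  }
  codons_to_stop <- if (g$strand == "+") {
    (g$end - min(pos, g$end)) %/% 3L
  } else {
    (max(pos, g$start) - g$start) %/% 3L
  }
  flagged <- reason != "none"
  tibble::tibble(
    gene_id = g$gene_id,
    is_potential_knockout = flagged,
    reason = reason,
    near_terminal = flagged && codons_to_stop <= near_terminal_codons,
    codons_to_stop = as.integer(codons_to_stop)
  )
}

#' Annotate a mutation table
#'
#' Adds `snp_class` (via [classify_snp()]; `NA` for non-SNP records) and,
#' when a reference annotation is supplied, the potential-knockout fields
#' for records mapped to genes.
#'
#' @param mutations Mutation table (see [read_mutation_table()] for the
#'   column schema).
#' @param annotation Optional reference `genome_annotation`.
#' @param genetic_code_id NCBI translation table identifier.
#' @param near_terminal_codons Passed to [flag_potential_knockout()].
#' @return The mutation tibble with added columns.
#' @export
annotate_mutations <- function(mutations, annotation = NULL,
                               genetic_code_id = "11",
                               near_terminal_codons = 5L) {
  mutations <- tibble::as_tibble(mutations)
  mutations$snp_class <- NA_character_
  is_snp <- mutations$category == "snp"
  if (any(is_snp)) {
    mutations$snp_class[is_snp] <- classify_snp(
      mutations$codon_from[is_snp], mutations$codon_to[is_snp],
      genetic_code_id
    )
  }
  if (!is.null(annotation)) {
    gene_tab <- annotation$genes
    n <- nrow(mutations)
    m <- match(mutations$gene_id, gene_tab$gene_id)
    known <- !is.na(m)
    g_start <- gene_tab$start[m]; g_end <- gene_tab$end[m]
    g_strand <- gene_tab$strand[m]
    pos <- mutations$position
    len <- if ("indel_length" %in% names(mutations)) {
      mutations$indel_length
    } else {
      rep(NA_integer_, n)
    }
    cat_ <- mutations$category
    bad_del <- known & cat_ == "large_deletion" & !is.na(len) &
      (pos + len - 1L < g_start | pos > g_end)
    if (any(bad_del)) {
      stop("large deletion(s) not overlapping their gene: record(s) ",
           paste(which(bad_del), collapse = ", "))
    }
    reason <- rep(NA_character_, n)
    reason[known] <- "none"
    reason[known & cat_ == "small_indel" & !is.na(len) & len %% 3L != 0L] <-
      "small_indel"
    reason[known & cat_ == "is_insertion"] <- "is_insertion"
    reason[known & cat_ == "large_deletion"] <- "large_deletion"
    codons_to_stop <- ifelse(g_strand == "+",
                             (g_end - pmin(pos, g_end)) %/% 3L,
                             (pmax(pos, g_start) - g_start) %/% 3L)
    flagged <- !is.na(reason) & reason != "none"
    mutations$is_potential_knockout <- ifelse(known, flagged, NA)
    mutations$reason <- reason
    mutations$near_terminal <- ifelse(known,
                                      flagged & codons_to_stop <= near_terminal_codons,
                                      NA)
    mutations$codons_to_stop <- as.integer(ifelse(known, codons_to_stop,
                                                  NA_integer_))
  }
  mutations
}

#' Count mutations per genome compartment
#'
#' Tallies mutations in the core and flexible compartments after optional
#' filtering on mutator context and SNP class (`"nonsynonymous"` includes
#' nonsense). Intergenic records are excluded; a counted gene without a
#' compartment label is an error.
#'
#' @param mutations Mutation table with `gene_id`, `mutator_context`, and —
#'   when filtering on class — `snp_class`.
#' @param partition A `core_partition`.
#' @param mutator_context Optional filter: `"nonmutator"` or `"mutator"`.
#' @param snp_class Optional filter: `"nonsynonymous"` or `"synonymous"`.
#' @return Named integer vector `c(core=, flexible=)`.
#' @export
tabulate_compartment_counts <- function(mutations, partition,
                                        mutator_context = NULL,
                                        snp_class = NULL) {
  m <- mutations[!is.na(mutations$gene_id) & mutations$gene_id != "", ]
  if (!is.null(mutator_context)) {
    m <- m[m$mutator_context == mutator_context, ]
  }
  if (!is.null(snp_class)) {
    keep <- if (snp_class == "nonsynonymous") {
      is_nonsynonymous(m$snp_class)
    } else {
      !is.na(m$snp_class) & m$snp_class == snp_class
    }
    m <- m[keep, ]
  }
  lab <- stats::setNames(partition$genes$compartment, partition$genes$gene_id)
  unknown <- setdiff(unique(m$gene_id), names(lab))
  if (length(unknown) > 0L) {
    stop("gene(s) without compartment label: ", paste(unknown, collapse = ", "))
  }
  comp <- lab[m$gene_id]
  c(core = sum(comp == "core"), flexible = sum(comp == "flexible"))
}

#' Collapse repeated observations of one mutational event
#'
#' Many clones from one population can carry the same mutation; analyses of
#' parallelism must count each independent event once. Records sharing an
#' `independent_event_id` are collapsed to one, keeping the earliest
#' observation (by generation, then clone id) and recording the observation
#' count.
#'
#' @param mutations Mutation table with `independent_event_id` populated.
#' @return Collapsed tibble with an added `n_observations` column.
#' @export
independent_event_collapse <- function(mutations) {
  if (anyNA(mutations$independent_event_id)) {
    stop("independent_event_id must be populated for every record")
  }
  conflicts <- mutations |>
    dplyr::group_by(.data$independent_event_id) |>
    dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene_id)) |>
    dplyr::filter(.data$n_genes > 1L)
  if (nrow(conflicts) > 0L) {
    stop("conflicting gene assignments within event id(s): ",
         paste(conflicts$independent_event_id, collapse = ", "))
  }
  mutations |>
    dplyr::group_by(.data$independent_event_id) |>
    dplyr::arrange(.data$generation, .data$clone_id, .by_group = TRUE) |>
    dplyr::mutate(n_observations = dplyr::n()) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

mutation_table_columns <- c(
  "population", "generation", "clone_id", "gene_id", "position", "category",
  "codon_from", "codon_to", "residue_index", "mutator_context",
  "on_line_of_descent", "independent_event_id"
)

#' Read and write mutation tables
#'
#' Tab-separated, one row per observed mutation, with the column schema
#' `population generation clone_id gene_id position category codon_from
#' codon_to residue_index mutator_context on_line_of_descent
#' independent_event_id` (extra columns such as `indel_length` or the
#' annotation fields are preserved). Missing values are written as `NA`.
#'
#' @param path File path.
#' @return `read_mutation_table()`: a tibble. `write_mutation_table()`:
#'   invisible `path`.
#' @export
read_mutation_table <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path, na.strings = "NA"))
  missing <- setdiff(mutation_table_columns, names(tab))
  if (length(missing) > 0L) {
    stop("mutation table missing column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_mutation_table
#' @param mutations Mutation tibble.
#' @export
write_mutation_table <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
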