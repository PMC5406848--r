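#' Bacterial genetic code with alternative initiators folded to Met
#'
#' Returns the bacterial/archaeal/plastid code (NCBI transl_table 11) as a
#' named character vector mapping codons to one-letter amino acids, with "*"
#' for stops.
#'
#' @param genetic_code_id NCBI translation table identifier (default "11").
#' @return Named character vector of length 64.
#' @export
genetic_code_table <- local({
  cache <- new.env(parent = emptyenv())
  function(genetic_code_id = "11") {
    key <- as.character(genetic_code_id)
    if (is.null(cache[[key]])) {
      cache[[key]] <- Biostrings::getGeneticCode(genetic_code_id)
    }
    cache[[key]]
  }
})

#' Translate a coding sequence
#'
#' Translates an in-frame CDS under the configured genetic code. The first
#' codon is translated as Met when it is one of the canonical bacterial
#' initiators (ATG, GTG, TTG). A single trailing stop codon is trimmed; an
#' internal stop is an error.
#'
#' @param nt_seq Character scalar, coding-strand nucleotide sequence with
#'   length divisible by 3.
#' @param genetic_code_id NCBI translation table identifier.
#' @return Character scalar protein sequence (stop excluded).
#' @export
translate_cds <- function(nt_seq, genetic_code_id = "11") {
  nt_seq <- toupper(nt_seq)
  if (nchar(nt_seq) %% 3L != 0L) {
    stop("CDS length (", nchar(nt_seq), ") is not divisible by 3")
  }
  code <- genetic_code_table(genetic_code_id)
  codons <- codon_split(nt_seq)
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    stop("invalid codon(s): ", paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  if (codons[1L] %in% c("ATG", "GTG", "TTG")) aa[1L] <- "M"
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) {
    stop("internal stop codon at codon position ",
         paste(which(aa == "*"), collapse = ", "))
  }
  paste(aa, collapse = "")
}

codon_split <- function(nt_seq) {
  n <- nchar(nt_seq)
  substring(nt_seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Construct a gene model
#'
#' A gene model is one row of a genome annotation: a CDS with 1-based
#' inclusive coordinates, a strand, the coding-strand nucleotide sequence and
#' its translation. Minus-strand genes store the reverse-complemented
#' (coding-strand) sequence, so `nchar(nt_seq) == end - start + 1` always
#' holds.
#'
#' @param gene_id,genome_id,contig Identifier strings.
#' @param start,end 1-based inclusive nucleotide coordinates, `end >= start`.
#' @param strand `"+"` or `"-"`.
#' @param nt_seq Coding-strand CDS sequence (length divisible by 3).
#' @param aa_seq Optional protein sequence; translated from `nt_seq` when
#'   omitted.
#' @param genetic_code_id NCBI translation table identifier.
#' @return A one-row tibble with class-invariant checks applied.
#' @export
gene_model <- function(gene_id, genome_id, contig, start, end, strand,
                       nt_seq, aa_seq = NULL, genetic_code_id = "11") {
  stopifnot(end >= start, strand %in% c("+", "-"))
  nt_seq <- toupper(nt_seq)
  if (nchar(nt_seq) != end - start + 1L) {
    stop("gene ", gene_id, ": nt_seq length ", nchar(nt_seq),
         " != end - start + 1 = ", end - start + 1L)
  }
  if (is.null(aa_seq)) aa_seq <- translate_cds(nt_seq, genetic_code_id)
  tibble::tibble(
    gene_id = gene_id, genome_id = genome_id, contig = contig,
    start = as.integer(start), end = as.integer(end), strand = strand,
    nt_seq = nt_seq, aa_seq = aa_seq
  )
}

#' Construct a genome annotation
#'
#' Bundles a genome's gene models with the derived total coding length.
#'
#' @param genome_id Identifier string.
#' @param genes Tibble of gene models (rows as produced by [gene_model()]).
#' @return A `genome_annotation` object: list with `genome_id`, `genes`,
#'   `total_coding_length`.
#' @export
genome_annotation <- function(genome_id, genes) {
  stopifnot(is.data.frame(genes))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_ids in genome ", genome_id, ": ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  structure(
    list(
      genome_id = genome_id,
      genes = tibble::as_tibble(genes),
      total_coding_length = sum(nchar(genes$nt_seq))
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, ": ", nrow(x$genes),
      " genes, ", x$total_coding_length, " coding bp\n", sep = "")
  invisible(x)
}

#' Extract a genome's proteome as a named character vector
#'
#' @param annotation A `genome_annotation`.
#' @return Named character vector of protein sequences (names = gene ids).
#' @export
proteome <- function(annotation) {
  stats::setNames(annotation$genes$aa_seq, annotation$genes$gene_id)
}

#' Read and write genome annotation files
#'
#' `write_genome_files()` emits per-genome protein FASTA, CDS FASTA and a
#' gene-coordinate TSV (`gene_id genome_id contig start end strand`);
#' `read_genome_files()` reconstructs the annotation from them.
#'
#' @param annotation A `genome_annotation`.
#' @param dir Output directory (created if needed).
#' @return `write_genome_files()`: invisible character vector of paths.
#'   `read_genome_files()`: a `genome_annotation`.
#' @export
write_genome_files <- function(annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gid <- annotation$genome_id
  paths <- file.path(dir, paste0(gid, c(".faa", ".fna", "_genes.tsv")))
  aa <- Biostrings::AAStringSet(stats::setNames(annotation$genes$aa_seq,
                                               annotation$genes$gene_id))
  nt <- Biostrings::DNAStringSet(stats::setNames(annotation$genes$nt_seq,
                                                 annotation$genes$gene_id))
  Biostrings::writeXStringSet(aa, paths[1])
  Biostrings::writeXStringSet(nt, paths[2])
  utils::write.table(
    annotation$genes[, c("gene_id", "genome_id", "contig", "start", "end", "strand")],
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}

#' @rdname write_genome_files
#' @param genome_id Genome identifier (file stem under `dir`).
#' @export
read_genome_files <- function(genome_id, dir) {
  aa <- Biostrings::readAAStringSet(file.path(dir, paste0(genome_id, ".faa")))
  nt <- Biostrings::readDNAStringSet(file.path(dir, paste0(genome_id, ".fna")))
  tab <- utils::read.delim(file.path(dir, paste0(genome_id, "_genes.tsv")),
                           colClasses = c(start = "integer", end = "integer"))
  tab <- tibble::as_tibble(tab)
  tab$nt_seq <- as.character(nt[tab$gene_id])
  tab$aa_seq <- as.character(aa[tab$gene_id])
  genome_annotation(genome_id, tab)
}
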