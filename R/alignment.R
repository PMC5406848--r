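#' Construct a protein alignment object
#'
#' @param rows Named character vector of equal-length aligned sequences over
#'   residues plus the gap symbol `-`.
#' @param family_id Optional family identifier.
#' @return A `protein_alignment`: list with `family_id`, `rows`, `n_columns`.
#' @export
protein_alignment <- function(rows, family_id = NA_character_) {
  stopifnot(length(rows) >= 2L, !is.null(names(rows)))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("aligned rows differ in length: ",
         paste(paste0(names(rows), "=", widths), collapse = ", "))
  }
  structure(list(family_id = family_id, rows = rows,
                 n_columns = unname(widths[1])),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> ", x$family_id, ": ", length(x$rows),
      " sequences x ", x$n_columns, " columns\n", sep = "")
  invisible(x)
}

alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment$rows, "", fixed = TRUE))
}

#' Align a protein family
#'
#' Built-in deterministic multiple aligner: global pairwise alignment for two
#' sequences, and a center-star progressive scheme for more (every sequence
#' is aligned to the center — the longest sequence, ties broken by name —
#' and the pairwise gap patterns are merged). Adequate for the moderately
#' diverged families this package analyses; pre-computed alignments can be
#' supplied instead via [load_alignment()] and always take precedence in the
#' pipeline.
#'
#' @param protein_sequences Named character vector, length >= 2.
#' @param family_id Optional identifier carried into the result.
#' @param gap_opening,gap_extension Gap penalties.
#' @param substitution_matrix Name of a Biostrings substitution matrix.
#' @return A `protein_alignment`; ungapping any row reproduces its input.
#' @export
align_family <- function(protein_sequences, family_id = NA_character_,
                         gap_opening = 10, gap_extension = 0.5,
                         substitution_matrix = "BLOSUM62") {
  seqs <- protein_sequences
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (any(bad)) {
    stop("non-residue characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  mat <- get_substitution_matrix(substitution_matrix)

  align_pair <- function(s1, s2) {
    al <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(s1), subject = Biostrings::AAString(s2),
      substitutionMatrix = mat, gapOpening = gap_opening,
      gapExtension = gap_extension, type = "global"
    )
    c(as.character(Biostrings::alignedPattern(al)),
      as.character(Biostrings::alignedSubject(al)))
  }

  if (length(seqs) == 2L) {
    p <- align_pair(seqs[[1]], seqs[[2]])
    aln <- protein_alignment(stats::setNames(p, names(seqs)), family_id)
  } else {
    ord <- order(-nchar(seqs), names(seqs))
    center_name <- names(seqs)[ord[1]]
    others <- setdiff(names(seqs), center_name)
    center <- seqs[[center_name]]
    L <- nchar(center)
    # per-slot gap counts: slot j = gaps inserted before center residue j,
    # slot L+1 = trailing gaps
    pair_rows <- list(); gap_counts <- list()
    for (nm in others) {
      p <- align_pair(center, seqs[[nm]])
      cc <- strsplit(p[1], "", fixed = TRUE)[[1]]
      oo <- strsplit(p[2], "", fixed = TRUE)[[1]]
      g <- integer(L + 1L); slot <- 1L
      res_chunks <- vector("list", L + 1L)
      buf <- character(0)
      for (k in seq_along(cc)) {
        if (cc[k] == "-") {
          g[slot] <- g[slot] + 1L
          buf <- c(buf, oo[k])
        } else {
          res_chunks[[slot]] <- c(buf, oo[k])
          buf <- character(0)
          slot <- slot + 1L
        }
      }
      res_chunks[[L + 1L]] <- buf
      pair_rows[[nm]] <- res_chunks
      gap_counts[[nm]] <- g
    }
    master <- Reduce(pmax, gap_counts)
    expand <- function(chunks, g) {
      out <- character(0)
      for (j in seq_len(L)) {
        seg <- chunks[[j]]
        ins <- seg[-length(seg)]
        out <- c(out, ins, rep("-", master[j] - length(ins)), seg[length(seg)])
      }
      tail_seg <- chunks[[L + 1L]]
      c(out, tail_seg, rep("-", master[L + 1L] - length(tail_seg)))
    }
    center_chars <- strsplit(center, "", fixed = TRUE)[[1]]
    center_row <- character(0)
    for (j in seq_len(L)) {
      center_row <- c(center_row, rep("-", master[j]), center_chars[j])
    }
    center_row <- c(center_row, rep("-", master[L + 1L]))
    rows <- c(stats::setNames(paste(center_row, collapse = ""), center_name),
              vapply(others, function(nm) {
                paste(expand(pair_rows[[nm]], gap_counts[[nm]]), collapse = "")
              }, character(1)))
    aln <- protein_alignment(rows[names(seqs)], family_id)
  }
  ungapped <- gsub("-", "", aln$rows, fixed = TRUE)
  stopifnot(identical(unname(ungapped), unname(seqs[names(aln$rows)])))
  aln
}

#' Load a pre-computed alignment from FASTA
#'
#' Validates equal row lengths and, when the unaligned sequences are given,
#' that ungapping each row reproduces its input exactly.
#'
#' @param path Aligned FASTA file.
#' @param family_id Optional identifier.
#' @param originals Optional named character vector of unaligned sequences
#'   to validate against.
#' @return A `protein_alignment`.
#' @export
load_alignment <- function(path, family_id = NA_character_, originals = NULL) {
  rows_set <- Biostrings::readAAStringSet(path)
  rows <- stats::setNames(as.character(rows_set), names(rows_set))
  aln <- protein_alignment(rows, family_id)
  if (!is.null(originals)) {
    ungapped <- gsub("-", "", aln$rows, fixed = TRUE)
    mism <- names(ungapped)[ungapped != originals[names(ungapped)]]
    if (length(mism) > 0L) {
      stop("aligned rows do not reproduce input sequences: ",
           paste(mism, collapse = ", "))
    }
  }
  aln
}

#' Map a residue index to its alignment column
#'
#' Converts a 1-based residue position in one (ungapped) sequence into the
#' alignment column holding that residue — e.g. to place an experimentally
#' observed mutation into a family alignment.
#'
#' @param alignment A `protein_alignment`.
#' @param genome_id Row name.
#' @param residue_index 1-based position within the ungapped row. May be a
#'   vector.
#' @return Integer column index (vectorized over `residue_index`).
#' @export
map_residue_to_column <- function(alignment, genome_id, residue_index) {
  if (!genome_id %in% names(alignment$rows)) {
    stop("no alignment row for ", genome_id)
  }
  chars <- strsplit(alignment$rows[[genome_id]], "", fixed = TRUE)[[1]]
  res_cols <- which(chars != "-")
  if (any(residue_index < 1L | residue_index > length(res_cols))) {
    stop("residue index out of range for ", genome_id,
         " (length ", length(res_cols), ")")
  }
  res_cols[residue_index]
}
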