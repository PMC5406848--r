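PROTEIN_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)
NUCLEIC_RESIDUES <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI")
WATER_RESIDUES <- c("HOH", "WAT", "DOD")

#' Parse a PDB structure
#'
#' Reads fixed-column ATOM/HETATM records (via bio3d, after a validation
#' pass that reports malformed coordinate fields with their line numbers).
#' Water molecules are dropped; for alternate locations the first conformer
#' (altloc blank or "A") is kept. Each chain is typed as `protein`,
#' `nucleic` or `ligand` from its residue names; hetero (non-water) atoms
#' are always treated as ligand atoms regardless of chain.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB text (one
#'   string with newlines, or one element per line).
#' @param structure_id Identifier (defaults to the file stem).
#' @return A `structure_model`: list with `structure_id`, `atoms` (tibble
#'   `chain`, `resno`, `insert`, `resid`, `elety`, `x`, `y`, `z`,
#'   `is_hetero`, `chain_type`) and `chain_types`.
#' @export
parse_structure <- function(pdb, structure_id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb)
    if (is.null(structure_id)) {
      structure_id <- tools::file_path_sans_ext(basename(pdb))
    }
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    if (is.null(structure_id)) structure_id <- "structure"
  }
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records found")
  for (ln in which(is_atom)) {
    coords <- substring(lines[ln], c(31, 39, 47), c(38, 46, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords))))) {
      stop("malformed coordinate field at line ", ln, ": ", lines[ln])
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb_obj <- bio3d::read.pdb(tmp, verbose = FALSE)
  a <- tibble::as_tibble(pdb_obj$atom)
  a <- a[!a$resid %in% WATER_RESIDUES, ]
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), ]
  if (nrow(a) == 0L) stop("no non-water atoms after filtering")
  a$chain[is.na(a$chain)] <- " "
  a$insert[is.na(a$insert)] <- ""
  atoms <- tibble::tibble(
    chain = a$chain, resno = as.integer(a$resno), insert = a$insert,
    resid = a$resid, elety = a$elety,
    x = a$x, y = a$y, z = a$z,
    is_hetero = a$type == "HETATM" | !(a$resid %in% c(PROTEIN_RESIDUES,
                                                      NUCLEIC_RESIDUES))
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  chain_types <- vapply(split(atoms, atoms$chain), function(ca) {
    polymer <- ca[!ca$is_hetero, ]
    if (any(polymer$resid %in% PROTEIN_RESIDUES)) "protein"
    else if (any(polymer$resid %in% NUCLEIC_RESIDUES)) "nucleic"
    else "ligand"
  }, character(1))
  atoms$chain_type <- unname(chain_types[atoms$chain])
  structure(list(structure_id = structure_id, atoms = atoms,
                 chain_types = chain_types),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$structure_id, ": ", nrow(x$atoms), " atoms, ",
      length(x$chain_types), " chain(s) [",
      paste(names(x$chain_types), x$chain_types, sep = ":", collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Map a query residue onto a structure chain
#'
#' Given a two-row alignment of the query protein against a structure
#' chain's sequence, returns the structure residue aligned to a query
#' residue. A query residue falling opposite a gap yields an explicit
#' unmapped result rather than silence.
#'
#' @param query_to_chain_alignment A two-row `protein_alignment`; the first
#'   row is the query, the second the structure chain sequence.
#' @param query_residue_index 1-based position in the ungapped query.
#' @param chain_id Chain identifier to report (default from the second row
#'   name).
#' @param chain_residue_numbers Author residue numbers of the chain in
#'   sequence order (default `1:n`, for structures numbered from 1).
#' @return Tibble with `query_residue`, `chain_id`, `residue_number`,
#'   `mapped` (FALSE with `NA` residue number when unmapped).
#' @export
map_residue <- function(query_to_chain_alignment, query_residue_index,
                        chain_id = NULL, chain_residue_numbers = NULL) {
  aln <- query_to_chain_alignment
  stopifnot(length(aln$rows) == 2L)
  if (is.null(chain_id)) chain_id <- names(aln$rows)[2]
  q_chars <- strsplit(aln$rows[[1]], "", fixed = TRUE)[[1]]
  c_chars <- strsplit(aln$rows[[2]], "", fixed = TRUE)[[1]]
  col <- map_residue_to_column(aln, names(aln$rows)[1], query_residue_index)
  chain_ord <- cumsum(c_chars != "-")
  if (is.null(chain_residue_numbers)) {
    chain_residue_numbers <- seq_len(max(chain_ord))
  }
  mapped <- c_chars[col] != "-"
  tibble::tibble(
    query_residue = query_residue_index,
    chain_id = chain_id,
    residue_number = ifelse(mapped,
                            chain_residue_numbers[chain_ord[col]],
                            NA_integer_),
    mapped = mapped
  )
}

#' Minimum distance from a residue to any binding partner
#'
#' Measures the minimum Euclidean distance from any atom of the target
#' residue to any partner atom — atoms outside the target's chain plus
#' ligand (hetero) atoms within it — and flags whether the residue lies
#' within the interface-proximity threshold (default 8 angstrom,
#' inclusive). All atoms present in the model are used.
#'
#' @param model A `structure_model`.
#' @param chain_id,residue_number Target residue (author numbering).
#' @param threshold Distance threshold in angstrom (default 8.0).
#' @return Tibble with `structure_id`, `chain_id`, `residue_number`,
#'   `partner_chain`, `partner_resno`, `partner_kind` (`protein`, `nucleic`
#'   or `ligand`), `min_distance`, `threshold`, `within_threshold`.
#' @export
min_distance_to_partners <- function(model, chain_id, residue_number,
                                     threshold = 8.0) {
  atoms <- model$atoms
  target <- atoms$chain == chain_id & atoms$resno == residue_number &
    !atoms$is_hetero
  if (!any(target)) {
    target <- atoms$chain == chain_id & atoms$resno == residue_number
  }
  if (!any(target)) {
    stop("residue ", residue_number, " not found in chain ", chain_id)
  }
  partner <- (atoms$chain != chain_id) | (atoms$is_hetero & !target)
  partner <- partner & !target
  if (!any(partner)) stop("monomeric structure, no partners")
  tx <- atoms$x[target]; ty <- atoms$y[target]; tz <- atoms$z[target]
  px <- atoms$x[partner]; py <- atoms$y[partner]; pz <- atoms$z[partner]
  d2 <- outer(tx, px, "-")^2 + outer(ty, py, "-")^2 + outer(tz, pz, "-")^2
  k <- arrayInd(which.min(d2), dim(d2))
  nearest <- which(partner)[k[2]]
  kind <- if (atoms$is_hetero[nearest]) "ligand" else atoms$chain_type[nearest]
  dmin <- sqrt(min(d2))
  tibble::tibble(
    structure_id = model$structure_id,
    chain_id = chain_id, residue_number = residue_number,
    partner_chain = atoms$chain[nearest],
    partner_resno = atoms$resno[nearest],
    partner_kind = kind,
    min_distance = dmin,
    threshold = threshold,
    within_threshold = dmin <= threshold
  )
}
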