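# three-letter -> one-letter codes for the 20 standard amino acids; anything
# else (MSE, ligands, unknowns) becomes 'X' so identity stays conservative
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

#' Read a macromolecular model from a PDB file
#'
#' Parses ATOM/HETATM records, resolves alternate locations by keeping the
#' highest-occupancy conformer (ties broken alphabetically, so 'A' wins), and
#' flags polymer atoms. Waters and ligands are retained but marked
#' non-polymer. Author residue numbering is kept as-is; no renumbering is
#' ever performed, so restraints emitted downstream address residues exactly
#' as they appear in the file.
#'
#' @param path Path to a PDB file.
#' @param id Label for the structure; defaults to the file name without
#'   extension.
#' @return An object of class \code{"pdb_structure"}: a list with \code{id}
#'   and \code{atoms}, a data frame with one row per atom (columns
#'   \code{type}, \code{chain}, \code{resno}, \code{ins}, \code{resid},
#'   \code{elety}, \code{elesy}, \code{x}, \code{y}, \code{z}, \code{o},
#'   \code{b}, \code{polymer}).
#' @seealso [write_structure()], [extract_chain_sequence()]
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path))
    stop_lrr("io_error", "file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop_lrr("format_error", "cannot parse PDB file '",
                                 path, "': ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop_lrr("format_error", "no atom records in '", path, "'")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at$chain[is.na(at$chain)] <- " "
  # altloc: keep the highest-occupancy conformer per atom site, tie -> 'A'
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]

  elesy <- at$elesy
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[bad] <- substr(gsub("[0-9]", "", at$elety[bad]), 1, 1)
  polymer <- at$type == "ATOM" & !(at$resid %in% WATER_RESID)
  atoms <- data.frame(
    type = at$type, chain = at$chain, resno = as.integer(at$resno),
    ins = at$insert, resid = at$resid, elety = at$elety,
    elesy = toupper(trimws(elesy)),
    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
    polymer = polymer, stringsAsFactors = FALSE)
  if (!any(atoms$polymer))
    stop_lrr("empty_model", "no polymer chains in '", path,
             "' (only waters/heteroatoms found)")
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  new_structure(atoms, id = id)
}

# constructor shared by the reader and the synthetic generators
new_structure <- function(atoms, id = "model") {
  stopifnot(is.data.frame(atoms))
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "pdb_structure")
}

#' Write a structure to a PDB file
#'
#' Inverse of [read_structure()]: coordinates survive a round trip to the
#' fixed-width PDB precision (3 decimals). Residue numbers outside the
#' fixed-width PDB range are rejected rather than wrapped.
#'
#' @param structure A \code{"pdb_structure"}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(structure, path) {
  check_structure(structure)
  at <- structure$atoms
  if (nrow(at) == 0)
    stop_lrr("empty_model", "refusing to write an empty structure")
  if (any(at$resno > 9999L | at$resno < -999L))
    stop_lrr("format_error",
             "residue numbers outside the fixed-width PDB range [-999, 9999]")
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
      type = at$type, resno = at$resno, resid = at$resid,
      eleno = seq_len(nrow(at)), elety = at$elety, chain = at$chain,
      insert = ifelse(nzchar(at$ins), at$ins, NA), o = at$o, b = at$b,
      elesy = at$elesy)
    TRUE
  }, error = function(e) stop_lrr("io_error", "cannot write '", path, "': ",
                                  conditionMessage(e)))
  invisible(path)
}

#' Extract the one-letter sequence of a polymer chain
#'
#' One letter per polymer residue in order of appearance; nonstandard
#' residues map to \code{'X'}.
#'
#' @param structure A \code{"pdb_structure"}.
#' @param chain_id Chain identifier.
#' @return Single character string.
#' @export
extract_chain_sequence <- function(structure, chain_id) {
  res <- residue_table(structure, chain_id)
  paste(ifelse(res$resid %in% names(AA_3TO1), AA_3TO1[res$resid], "X"),
        collapse = "")
}

#' Polymer chain identifiers of a structure
#' @param structure A \code{"pdb_structure"}.
#' @return Character vector of chain ids, in order of first appearance.
#' @export
chain_ids <- function(structure) {
  check_structure(structure)
  unique(structure$atoms$chain[structure$atoms$polymer])
}

#' Per-residue table of a polymer chain
#'
#' @param structure A \code{"pdb_structure"}.
#' @param chain_id Chain identifier.
#' @return Data frame with one row per residue (\code{resno}, \code{ins},
#'   \code{resid}) in order of appearance.
#' @export
residue_table <- function(structure, chain_id) {
  check_structure(structure)
  at <- structure$atoms
  sel <- at$polymer & at$chain == chain_id
  if (!any(sel))
    stop_lrr("lookup_error", "no polymer chain '", chain_id, "' in structure '",
             structure$id, "'")
  at <- at[sel, , drop = FALSE]
  key <- paste(at$resno, at$ins, sep = "\r")
  first <- !duplicated(key)
  data.frame(resno = at$resno[first], ins = at$ins[first],
             resid = at$resid[first], stringsAsFactors = FALSE)
}

# coordinates of one named atom per residue of a chain, NA rows when absent;
# residues given as a residue_table()-style data frame
atom_coords_by_residue <- function(structure, chain_id, residues, atom_name) {
  at <- structure$atoms
  sel <- at$polymer & at$chain == chain_id & at$elety == atom_name
  at <- at[sel, , drop = FALSE]
  idx <- match(paste(residues$resno, residues$ins, sep = "\r"),
               paste(at$resno, at$ins, sep = "\r"))
  cbind(at$x[idx], at$y[idx], at$z[idx])
}

coords_matrix <- function(structure, rows = NULL) {
  at <- structure$atoms
  if (!is.null(rows)) at <- at[rows, , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

check_structure <- function(x) {
  if (!inherits(x, "pdb_structure"))
    stop_lrr("type_error", "expected a 'pdb_structure' object")
  invisible(x)
}

#' @export
print.pdb_structure <- function(x, ...) {
  at <- x$atoms
  ch <- chain_ids(x)
  nres <- sum(vapply(ch, function(c) nrow(residue_table(x, c)), 1L))
  cat(sprintf("<pdb_structure '%s'> %d atoms, %d polymer residues, chain(s) %s\n",
              x$id, nrow(at), nres, paste(ch, collapse = ", ")))
  invisible(x)
}
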