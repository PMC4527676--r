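#' Coordinate traces: one chain's C-alpha backbone
#'
#' A `coord_trace` holds the ordered C-alpha trace of one protein chain:
#' authored residue numbers (with insertion codes), one-letter amino-acid
#' codes, and 3D coordinates in Angstrom. It is the carrier for all
#' structure-based computations (intramolecular distance matrices, per-site
#' dRMSD, superposition).
#'
#' @param structure_id Short identifier (e.g. a PDB code).
#' @param chain_id Single chain character.
#' @param residues Tibble with columns `residue_number` (integer),
#'   `insertion_code` (character, `""` when absent), `amino_acid`
#'   (1-letter code) and `x`, `y`, `z` (Angstrom).
#' @return An object of class `coord_trace`.
#' @export
coord_trace <- function(structure_id, chain_id, residues) {
  residues <- tibble::as_tibble(residues)
  needed <- c("residue_number", "insertion_code", "amino_acid", "x", "y", "z")
  if (!all(needed %in% names(residues))) {
    abort_globinkit(
      paste("residues must have columns:", paste(needed, collapse = ", ")),
      "globinkit_bad_input"
    )
  }
  if (nrow(residues) == 0) {
    abort_globinkit("empty trace", "globinkit_empty_trace")
  }
  key <- paste(residues$residue_number, residues$insertion_code)
  if (anyDuplicated(key)) {
    abort_globinkit("duplicate (residue_number, insertion_code) in trace",
                    "globinkit_bad_input")
  }
  if (!all(is.finite(residues$x) & is.finite(residues$y) & is.finite(residues$z))) {
    abort_globinkit("non-finite coordinates in trace", "globinkit_bad_input")
  }
  structure(
    list(structure_id = structure_id, chain_id = chain_id, residues = residues),
    class = "coord_trace"
  )
}

#' @export
print.coord_trace <- function(x, ...) {
  cat(sprintf("<coord_trace> %s chain %s: %d residues\n",
              x$structure_id, x$chain_id, nrow(x$residues)))
  invisible(x)
}

#' @export
length.coord_trace <- function(x) nrow(x$residues)

#' C-alpha coordinates of a trace as an n x 3 matrix
#' @param trace A [coord_trace()].
#' @return Numeric matrix with one row per residue.
#' @export
trace_xyz <- function(trace) {
  stopifnot(inherits(trace, "coord_trace"))
  as.matrix(trace$residues[, c("x", "y", "z")])
}

#' One-letter sequence of a trace
#' @param trace A [coord_trace()].
#' @return Single string of 1-letter codes.
#' @export
trace_sequence <- function(trace) {
  paste(trace$residues$amino_acid, collapse = "")
}

#' Read a C-alpha trace from PDB-format text
#'
#' Parses PDB text (via bio3d) and extracts the C-alpha trace of one chain.
#' Only the first MODEL is used. Alternate locations are resolved by highest
#' occupancy (ties: first encountered). HETATM residues are excluded except
#' selenomethionine (MSE), which is mapped to `M`. Non-standard residues map
#' to `X`.
#'
#' @param pdb_text PDB-format text (single string or lines) or a file path.
#' @param chain Chain identifier; default is the first chain (in file order)
#'   containing at least one C-alpha.
#' @param structure_id Identifier stored on the trace; defaults to "pdb".
#' @return A [coord_trace()].
#' @export
read_structure <- function(pdb_text, chain = NULL, structure_id = "pdb") {
  path <- pdb_text
  if (!(length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text))) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb_text) == 1) strsplit(pdb_text, "\n")[[1]] else pdb_text,
               path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  keep <- at$elety == "CA" &
    (at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) {
    abort_globinkit("empty trace: no C-alpha atoms found", "globinkit_empty_trace")
  }
  chains <- unique(at$chain)
  if (is.null(chain)) {
    chain <- chains[[1]]
  } else if (!chain %in% chains) {
    abort_globinkit(sprintf("chain not found: '%s'", chain),
                    "globinkit_chain_not_found")
  }
  at <- at[at$chain == chain, , drop = FALSE]
  ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$resno, ins)
  # altloc: keep highest occupancy per residue, ties -> first encountered
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(match(key, unique(key)), -occ)
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  ins <- ifelse(is.na(at$insert), "", at$insert)
  aa <- unname(AA_THREE_TO_ONE[at$resid])
  aa[is.na(aa)] <- "X"
  coord_trace(
    structure_id = structure_id,
    chain_id = chain,
    residues = tibble::tibble(
      residue_number = as.integer(at$resno),
      insertion_code = ins,
      amino_acid = aa,
      x = at$x, y = at$y, z = at$z
    )
  )
}
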