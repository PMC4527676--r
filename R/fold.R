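# Myoglobin-fold validation: template positions, helix annotation keyed to
# sperm whale myoglobin, fold checks, and helix-relative intron notation.

#' Sperm whale myoglobin reference sequence
#'
#' The 153-residue mature sperm whale myoglobin sequence used as the default
#' fold reference (distal His at E7 = residue 64, proximal His at F8 =
#' residue 93, CD1 Phe at residue 43).
#'
#' @return A single string of 153 one-letter codes.
#' @export
mb_reference_sequence <- function() {
  paste0(
    "VLSEGEWQLVLHVWAKVEADVAGHGQDILIRLFKSHPETLEKFDRFKHLKTEAEMKASED",
    "LKKHGVTVLTALGAILKKKGHHEAELKPLAQSHATKHKIPIKYLEFISEAIIHVLHSRHP",
    "GDFGADAQGAMNKALELFRKDIAAKYKELGYQG"
  )
}

#' Helix annotation for the myoglobin reference
#'
#' Maps every residue of the sperm whale myoglobin reference to a helix
#' (A-H) or inter-helical segment (AB, CD, EF, FG, GH) with its 1-based
#' index within that segment, yielding labels such as `B12`, `CD1`, `F8`.
#' Residues before helix A are labelled `pre-A`, after helix H `post-H`.
#'
#' @param reference_id Id the annotation is keyed to (for bookkeeping).
#' @return A tibble with columns `residue_number`, `segment`, `index`,
#'   `label`, plus attribute `reference_id`.
#' @export
mb_helix_annotation <- function(reference_id = "spermwhale_Mb") {
  bounds <- list(
    `pre-A` = 1:2,  A = 3:18,   AB = 19,     B = 20:35,  C = 36:42,
    CD = 43:50,     D = 51:57,  E = 58:77,   EF = 78:85, F = 86:94,
    FG = 95:99,     G = 100:118, GH = 119:124, H = 125:148, `post-H` = 149:153
  )
  ann <- purrr::imap_dfr(bounds, function(res, seg) {
    tibble::tibble(residue_number = as.integer(res), segment = seg,
                   index = seq_along(res))
  })
  ann <- dplyr::arrange(ann, .data$residue_number)
  ann$label <- ifelse(ann$segment %in% c("pre-A", "post-H"),
                      ann$segment, paste0(ann$segment, ann$index))
  attr(ann, "reference_id") <- reference_id
  ann
}

#' Myoglobin-fold position template
#'
#' The conserved, predominantly hydrophobic, solvent-inaccessible positions
#' that define the 3/3 myoglobin fold, named helix-relative (e.g. `A8`,
#' `CD1`, `F8`). Two variants are shipped: the default 36-position list
#' (33 intra-helical positions, CD1 and FG4, and the invariant proximal
#' His at F8) and a 37-position variant that uses C5 instead of C4 and adds
#' CD4.
#'
#' @param variant `"methods"` (36 positions, default) or `"s1fig"`
#'   (37 positions).
#' @param hydrophobic_set Residues counted as hydrophobic.
#' @param min_hydrophobic_fraction Minimum fraction of observed template
#'   positions (F8 excluded) that must be hydrophobic for the "predominantly
#'   hydrophobic" reading of the fold.
#' @return A list of class `mb_fold_template` with elements `positions`
#'   (tibble: `label`, `helix`, `role`), `hydrophobic_set`,
#'   `min_hydrophobic_fraction`.
#' @export
mb_fold_template <- function(variant = c("methods", "s1fig"),
                             hydrophobic_set = c("A", "C", "F", "I", "L",
                                                 "M", "V", "W", "Y"),
                             min_hydrophobic_fraction = 0.70) {
  variant <- match.arg(variant)
  intra <- c("A8", "A11", "A12", "A15",
             "B6", "B9", "B10", "B13", "B14",
             if (variant == "methods") "C4" else "C5",
             "E4", "E7", "E8", "E11", "E12", "E15", "E18", "E19",
             "F1", "F4",
             "G5", "G8", "G11", "G12", "G13", "G15", "G16",
             "H7", "H8", "H11", "H12", "H15", "H19")
  inter <- c("CD1", if (variant == "s1fig") "CD4", "FG4")
  labels <- c(intra, inter, "F8")
  roles <- c(rep("intra", length(intra)), rep("inter", length(inter)), "F8_his")
  positions <- tibble::tibble(
    label = labels,
    helix = sub("^([A-H]+).*$", "\\1", labels),
    role = roles
  )
  if (sum(positions$label == "F8") != 1) {
    abort_globinkit("template must contain F8 exactly once", "globinkit_bad_input")
  }
  if (anyDuplicated(positions$label)) {
    abort_globinkit("template labels must be unique", "globinkit_bad_input")
  }
  structure(
    list(positions = positions, hydrophobic_set = hydrophobic_set,
         min_hydrophobic_fraction = min_hydrophobic_fraction,
         variant = variant),
    class = "mb_fold_template"
  )
}

#' Is a residue hydrophobic under a fold template?
#'
#' @param residue One-letter code (vectorised). `X` never counts.
#' @param template A [mb_fold_template()].
#' @return Logical vector.
#' @export
classify_hydrophobic <- function(residue, template = mb_fold_template()) {
  bad <- setdiff(unique(residue), c(AA_STANDARD, "X"))
  if (length(bad) > 0) {
    abort_globinkit(
      sprintf("invalid residue code(s): %s", paste(bad, collapse = ", ")),
      "globinkit_invalid_residue"
    )
  }
  residue %in% template$hydrophobic_set
}

#' Check a candidate sequence against the myoglobin-fold criteria
#'
#' Given an alignment containing the annotated reference and one candidate,
#' resolves every template position to the candidate residue (or gap) in
#' that column and applies the globin acceptance rule: an His at the
#' proximal F8 position, presence of helices B, C, E, F and G (at least
#' half of the template positions of each helix occupied by a candidate
#' residue; helix D carries no template positions and genuinely lacks
#' density in some true globins), and — unless `strict = TRUE` — a
#' predominantly hydrophobic template profile. When a structure-profile
#' Z-score is supplied as input metadata, passing additionally requires
#' `fugue_z > 6`; the score is never computed here.
#'
#' @param aln A [struct_alignment()] built from sequences (e.g. by
#'   [read_gapped_alignment()]) containing the reference and the candidate.
#' @param template A [mb_fold_template()].
#' @param annotation Reference helix annotation ([mb_helix_annotation()]).
#' @param reference_id Alignment member holding the annotated reference.
#' @param candidate_id Alignment member to check; defaults to the single
#'   non-reference member.
#' @param fugue_z Optional externally computed structure-profile Z-score.
#' @param strict If `TRUE`, enforce only the F8-His + helix-coverage rule
#'   (plus the Z-score when given), not the hydrophobic fraction.
#' @return An object of class `fold_check` (see [tidy.fold_check()] /
#'   [glance.fold_check()]) with the per-position table, helix coverage,
#'   hydrophobic fraction and the overall `verdict`.
#' @export
check_mb_fold <- function(aln, template = mb_fold_template(),
                          annotation = mb_helix_annotation(),
                          reference_id = "spermwhale_Mb",
                          candidate_id = NULL, fugue_z = NULL,
                          strict = FALSE) {
  stopifnot(inherits(aln, "struct_alignment"))
  if (is.null(aln$rows)) {
    abort_globinkit("alignment must carry sequence rows", "globinkit_bad_input")
  }
  if (!reference_id %in% aln$member_ids) {
    abort_globinkit(sprintf("reference '%s' not in alignment", reference_id),
                    "globinkit_bad_input")
  }
  if (is.null(candidate_id)) {
    others <- setdiff(aln$member_ids, reference_id)
    if (length(others) != 1) {
      abort_globinkit("alignment must contain the reference and exactly one candidate (or give candidate_id)",
                      "globinkit_bad_input")
    }
    candidate_id <- others
  }
  ref_ord <- aln$ordinals[, reference_id]
  cand_chars <- chars(aln$rows[[candidate_id]])

  pos <- template$positions
  resolved <- purrr::pmap_dfr(pos, function(label, helix, role) {
    hit <- annotation$residue_number[annotation$label == label]
    if (length(hit) != 1) {
      abort_globinkit(sprintf("annotation incomplete: no residue for template label '%s'", label),
                      "globinkit_annotation_incomplete")
    }
    col <- which(!is.na(ref_ord) & ref_ord == hit)
    if (length(col) != 1) {
      abort_globinkit(sprintf("annotation incomplete: reference lacks residue %d (label '%s')", hit, label),
                      "globinkit_annotation_incomplete")
    }
    res <- cand_chars[[col]]
    gap <- is_gap_char(res)
    tibble::tibble(
      label = label, helix = helix, role = role,
      reference_residue = hit, column = col,
      residue = ifelse(gap, NA_character_, res),
      hydrophobic = if (gap) NA else classify_hydrophobic(res, template)
    )
  })

  f8_row <- resolved[resolved$role == "F8_his", ]
  f8_his <- !is.na(f8_row$residue) && f8_row$residue == "H"

  helix_rows <- resolved[resolved$helix %in% LETTERS[1:8] & resolved$role != "F8_his", ]
  coverage <- helix_rows |>
    dplyr::group_by(.data$helix) |>
    dplyr::summarise(frac = mean(!is.na(.data$residue)), .groups = "drop")
  # F8 occupancy contributes to helix F coverage
  f_frac <- mean(!is.na(resolved$residue[resolved$helix == "F"]))
  coverage$frac[coverage$helix == "F"] <- f_frac
  helices_present <- coverage$helix[coverage$frac >= 0.5]
  required <- c("B", "C", "E", "F", "G")
  helices_ok <- all(required %in% helices_present)

  hp_rows <- resolved[resolved$role != "F8_his" & !is.na(resolved$residue), ]
  hydrophobic_fraction <- if (nrow(hp_rows) == 0) 0 else mean(hp_rows$hydrophobic)

  verdict <- f8_his && helices_ok &&
    (strict || hydrophobic_fraction >= template$min_hydrophobic_fraction) &&
    (is.null(fugue_z) || fugue_z > 6)

  structure(
    list(positions = resolved, f8_his = f8_his,
         helices_present = helices_present,
         hydrophobic_fraction = hydrophobic_fraction,
         fugue_z = fugue_z, strict = strict, verdict = verdict,
         candidate_id = candidate_id, reference_id = reference_id,
         template_variant = template$variant,
         min_hydrophobic_fraction = template$min_hydrophobic_fraction),
    class = "fold_check"
  )
}

#' @export
print.fold_check <- function(x, ...) {
  cat(sprintf("<fold_check> %s vs %s: %s\n", x$candidate_id, x$reference_id,
              if (x$verdict) "PASS" else "FAIL"))
  cat(sprintf("  F8 His: %s | helices present: %s | hydrophobic fraction: %.2f%s\n",
              x$f8_his, paste(x$helices_present, collapse = ""),
              x$hydrophobic_fraction,
              if (is.null(x$fugue_z)) "" else sprintf(" | Z = %.2f", x$fugue_z)))
  invisible(x)
}

#' Map a CDS intron offset to helix-relative notation
#'
#' Converts a nucleotide offset within a candidate's coding sequence to the
#' field's helix-relative intron notation: helix letter + residue index
#' within the helix + phase, e.g. `B12.2` (between positions 2 and 3 of the
#' codon of helix-B residue 12) or `G7.0` (exactly between the codons of
#' helix-G residues 6 and 7). Phase 0 means the intron falls between codons;
#' the downstream residue is named. Offsets mapping outside annotated
#' helices return the flanking-segment label (`pre-A`, `CD`, ..., `post-H`).
#'
#' @param cds_offset_nt Intron position: number of coding nucleotides before
#'   the intron, in `[1, 3 * protein_length)`.
#' @param aln Candidate-to-reference [struct_alignment()] (sequence rows).
#' @param annotation Reference helix annotation ([mb_helix_annotation()]).
#' @param reference_id,candidate_id Alignment member ids (candidate defaults
#'   to the single non-reference member).
#' @return Notation string such as `"B12.2"`.
#' @export
map_intron_position <- function(cds_offset_nt, aln,
                                annotation = mb_helix_annotation(),
                                reference_id = "spermwhale_Mb",
                                candidate_id = NULL) {
  stopifnot(inherits(aln, "struct_alignment"))
  if (is.null(candidate_id)) {
    others <- setdiff(aln$member_ids, reference_id)
    if (length(others) != 1) {
      abort_globinkit("give candidate_id when the alignment has several candidates",
                      "globinkit_bad_input")
    }
    candidate_id <- others
  }
  cand_ord <- aln$ordinals[, candidate_id]
  ref_ord <- aln$ordinals[, reference_id]
  prot_len <- max(cand_ord, na.rm = TRUE)
  if (cds_offset_nt < 1 || cds_offset_nt >= 3 * prot_len) {
    abort_globinkit(sprintf("cds_offset_nt must lie in [1, %d)", 3 * prot_len),
                    "globinkit_bad_input")
  }
  phase <- cds_offset_nt %% 3
  residue <- cds_offset_nt %/% 3 + 1  # phase 0: downstream residue is named
  col <- which(!is.na(cand_ord) & cand_ord == residue)
  ref_res <- if (length(col) == 1) ref_ord[[col]] else NA_integer_
  if (is.na(ref_res)) {
    # insertion relative to the reference: attach to the nearest preceding
    # aligned reference residue's segment
    prev <- which(!is.na(cand_ord) & !is.na(ref_ord) & cand_ord < residue)
    if (length(prev) == 0) return(paste0("pre-A.", phase))
    ref_res <- ref_ord[[max(prev)]]
  }
  row <- annotation[annotation$residue_number == ref_res, ]
  if (nrow(row) != 1) {
    abort_globinkit("annotation incomplete: reference residue not annotated",
                    "globinkit_annotation_incomplete")
  }
  if (row$segment %in% c("pre-A", "post-H")) {
    return(paste0(row$segment, ".", phase))
  }
  paste0(row$segment, row$index, ".", phase)
}
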