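#' Structure/sequence alignments over residue ordinals
#'
#' A `struct_alignment` maps each member (a sequence or a structure trace) to
#' a residue ordinal in every alignment column, or to a gap (`NA`). Ordinals
#' are 1-based indices into the member's residue list / ungapped sequence.
#' An optional per-column confidence track in \eqn{[0,1]} can be attached
#' (e.g. the column confidences emitted by a joint structural aligner).
#'
#' @param ordinals Integer matrix, columns of the alignment in rows, one
#'   column per member (named); `NA` marks a gap.
#' @param confidence Optional numeric vector, one value in \eqn{[0,1]} per
#'   alignment column.
#' @param rows Optional named character vector of gapped row strings (kept
#'   when the alignment was built from sequences, so residues can be read
#'   back per column).
#' @return An object of class `struct_alignment`.
#' @export
struct_alignment <- function(ordinals, confidence = NULL, rows = NULL) {
  ordinals <- as.matrix(ordinals)
  if (is.null(colnames(ordinals))) {
    abort_globinkit("ordinal matrix must have member ids as column names",
                    "globinkit_bad_input")
  }
  storage.mode(ordinals) <- "integer"
  for (m in colnames(ordinals)) {
    v <- ordinals[, m]
    v <- v[!is.na(v)]
    if (length(v) > 1 && any(diff(v) <= 0)) {
      abort_globinkit(
        sprintf("ordinals for member '%s' must strictly increase down the columns", m),
        "globinkit_bad_input"
      )
    }
  }
  if (!is.null(confidence)) {
    if (length(confidence) != nrow(ordinals)) {
      abort_globinkit(
        sprintf("confidence length (%d) does not match column count (%d)",
                length(confidence), nrow(ordinals)),
        "globinkit_bad_input"
      )
    }
    if (any(!is.finite(confidence)) || any(confidence < 0 | confidence > 1)) {
      abort_globinkit("confidence values must lie in [0, 1]", "globinkit_bad_input")
    }
  }
  structure(
    list(member_ids = colnames(ordinals), ordinals = ordinals,
         confidence = confidence, rows = rows),
    class = "struct_alignment"
  )
}

#' @export
print.struct_alignment <- function(x, ...) {
  cat(sprintf("<struct_alignment> %d columns, %d members: %s\n",
              nrow(x$ordinals), length(x$member_ids),
              paste(x$member_ids, collapse = ", ")))
  if (!is.null(x$confidence)) cat("  with per-column confidence\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln A [struct_alignment()].
#' @export
n_columns <- function(aln) nrow(aln$ordinals)

#' Read a gapped FASTA alignment
#'
#' Builds a [struct_alignment()] from gapped FASTA text. Both `-` and `.`
#' count as gaps. All rows must have equal length.
#'
#' @param text Gapped FASTA text or a path (see [read_fasta()]).
#' @return A `struct_alignment` whose members are the FASTA records; the
#'   gapped rows are retained so per-column residues can be recovered.
#' @export
read_gapped_alignment <- function(text) {
  recs <- read_fasta(text, allow_gaps = TRUE)
  widths <- nchar(recs$sequence)
  if (length(unique(widths)) != 1) {
    abort_globinkit("alignment rows differ in length", "globinkit_ragged_alignment")
  }
  if (anyDuplicated(recs$id)) {
    abort_globinkit("duplicate member ids in alignment", "globinkit_bad_input")
  }
  ords <- vapply(recs$sequence, function(s) {
    cc <- chars(s)
    gap <- is_gap_char(cc)
    v <- cumsum(!gap)
    v[gap] <- NA_integer_
    as.integer(v)
  }, integer(widths[[1]]))
  if (is.null(dim(ords))) ords <- matrix(ords, ncol = nrow(recs))
  colnames(ords) <- recs$id
  rows <- stats::setNames(recs$sequence, recs$id)
  struct_alignment(ords, rows = rows)
}

#' Read a per-column confidence track from TSV text
#'
#' Expects a single-header-row TSV with a `confidence` column (a bare single
#' column of values under any single header is also accepted).
#'
#' @param text TSV text (string or lines) or a path.
#' @return Numeric vector of confidences in \eqn{[0,1]}.
#' @export
read_confidence <- function(text) {
  lines <- fasta_lines(text)
  if (length(lines) == 0 || !any(nzchar(trimws(lines)))) {
    abort_globinkit("empty confidence input", "globinkit_empty_input")
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          header = TRUE, sep = "\t", check.names = FALSE)
  col <- if ("confidence" %in% names(df)) df$confidence else df[[1]]
  col <- as.numeric(col)
  if (any(!is.finite(col)) || any(col < 0 | col > 1)) {
    abort_globinkit("confidence values must lie in [0, 1]", "globinkit_bad_input")
  }
  col
}

#' Attach a confidence track to an alignment
#'
#' @param aln A [struct_alignment()].
#' @param confidence Numeric vector, one value per column.
#' @return The alignment with confidence attached.
#' @export
set_confidence <- function(aln, confidence) {
  stopifnot(inherits(aln, "struct_alignment"))
  struct_alignment(aln$ordinals, confidence = confidence, rows = aln$rows)
}

#' Columns aligned (non-gap) in two named members
#' @noRd
both_aligned <- function(aln, a, b) {
  for (m in c(a, b)) {
    if (!m %in% aln$member_ids) {
      abort_globinkit(sprintf("member '%s' not in alignment", m),
                      "globinkit_bad_input")
    }
  }
  which(!is.na(aln$ordinals[, a]) & !is.na(aln$ordinals[, b]))
}

#' Length of the region aligned between two members
#'
#' Counts alignment columns in which both members are non-gap (the `n` of
#' the per-site dRMSD statistic).
#'
#' @param aln A [struct_alignment()].
#' @param a,b Member ids.
#' @return Integer count.
#' @export
aligned_length <- function(aln, a, b) {
  length(both_aligned(aln, a, b))
}
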