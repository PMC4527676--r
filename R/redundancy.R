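# Percent-identity matrices from an MSA and greedy redundancy reduction.

#' Percent identity between two aligned rows
#'
#' Identity is computed over comparable columns only: columns where both
#' rows carry a residue (no gap). `X` never matches anything, including
#' another `X`. With `denominator = "alignment"` the full alignment length
#' is used instead of the comparable-column count.
#'
#' @param a,b Gapped row strings of equal length.
#' @param denominator `"comparable"` (default) or `"alignment"`.
#' @return Percent identity in \eqn{[0, 100]}, or `NA` when no column is
#'   comparable.
#' @export
percent_identity <- function(a, b, denominator = c("comparable", "alignment")) {
  denominator <- match.arg(denominator)
  if (nchar(a) != nchar(b)) {
    abort_globinkit("aligned rows differ in length", "globinkit_ragged_alignment")
  }
  ca <- chars(a); cb <- chars(b)
  comparable <- !is_gap_char(ca) & !is_gap_char(cb)
  ident <- comparable & ca == cb & ca != "X"
  denom <- if (denominator == "comparable") sum(comparable) else length(ca)
  if (sum(comparable) == 0) return(NA_real_)
  100 * sum(ident) / denom
}

#' Pairwise percent-identity matrix of an MSA
#'
#' @param msa A [struct_alignment()] with sequence rows, a named character
#'   vector of gapped rows, or a tibble with `id` and `sequence` columns.
#' @param denominator Passed to [percent_identity()].
#' @return A symmetric numeric matrix (ids as dimnames) with diagonal
#'   exactly 100; incomparable pairs are `NA`.
#' @export
build_identity_matrix <- function(msa, denominator = c("comparable", "alignment")) {
  denominator <- match.arg(denominator)
  rows <- msa_rows(msa)
  n <- length(rows)
  if (n == 0) {
    abort_globinkit("empty alignment", "globinkit_empty_input")
  }
  m <- matrix(100, n, n, dimnames = list(names(rows), names(rows)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- percent_identity(rows[[i]], rows[[j]], denominator)
        m[i, j] <- m[j, i] <- v
      }
    }
  }
  m
}

#' Reduce sequence redundancy at an identity threshold
#'
#' Greedy Hobohm-1 sweep in input order: a sequence is kept iff its percent
#' identity to every previously kept sequence is strictly below the
#' threshold. Missing pairwise identities never force removal (treated as
#' 0%). The kept set is maximal: every removed sequence has identity at or
#' above the threshold to some kept sequence.
#'
#' @param matrix Symmetric percent-identity matrix with ids as dimnames
#'   (see [build_identity_matrix()]).
#' @param threshold_pct Identity threshold in `(0, 100]`.
#' @return Character vector of kept ids, in input order.
#' @export
reduce_redundancy <- function(matrix, threshold_pct = 90) {
  if (!is.numeric(threshold_pct) || length(threshold_pct) != 1 ||
      threshold_pct <= 0 || threshold_pct > 100) {
    abort_globinkit("threshold_pct must lie in (0, 100]", "globinkit_bad_input")
  }
  ids <- rownames(matrix)
  if (is.null(ids) || nrow(matrix) != ncol(matrix)) {
    abort_globinkit("matrix must be square with ids as dimnames",
                    "globinkit_bad_input")
  }
  m <- matrix
  m[is.na(m)] <- 0
  kept <- character(0)
  for (id in ids) {
    if (length(kept) == 0 || all(m[id, kept] < threshold_pct)) {
      kept <- c(kept, id)
    }
  }
  kept
}

#' Extract named gapped rows from the accepted MSA forms
#' @noRd
msa_rows <- function(msa) {
  if (inherits(msa, "struct_alignment")) {
    if (is.null(msa$rows)) {
      abort_globinkit("alignment does not carry sequence rows", "globinkit_bad_input")
    }
    return(msa$rows)
  }
  if (is.data.frame(msa)) {
    return(stats::setNames(toupper(msa$sequence), msa$id))
  }
  if (is.character(msa)) {
    if (length(msa) == 0) {
      abort_globinkit("empty alignment", "globinkit_empty_input")
    }
    if (is.null(names(msa))) names(msa) <- paste0("seq", seq_along(msa))
    return(toupper(msa))
  }
  abort_globinkit("cannot interpret input as an MSA", "globinkit_bad_input")
}
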