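# Tandem globin-domain detection by iterated local alignment.

#' Scan a protein for tandem globin domains
#'
#' Finds repeated globin domains in a long (possibly chimeric, multidomain)
#' protein by iterated Smith-Waterman alignment against a single-domain
#' probe (default: sperm whale myoglobin): the best local hit with score at
#' least `min_score` is recorded, its span is excluded, and the flanking
#' segments are re-scanned until no qualifying hit remains. Scoring uses
#' BLOSUM62 with affine gap penalties (open 11, extend 1). Calls are trimmed
#' to the probe-covered span and restricted to plausible single-domain
#' lengths.
#'
#' @param query Query protein: a string, a named length-1 character vector,
#'   or a one-row tibble with `id`/`sequence`.
#' @param probe Single-domain probe sequence (same forms). Default sperm
#'   whale myoglobin.
#' @param min_score Minimum local alignment score to accept a hit.
#' @param min_len,max_len Accepted domain span lengths (residues); globin
#'   domains run roughly 110-160 residues.
#' @param probe_f8 Probe residue index of the proximal F8 His (93 for the
#'   default probe); used to flag whether each call carries an His aligned
#'   to F8. `NA` skips the flag.
#' @return A tibble of domain calls sorted by `start`: columns `start`,
#'   `end` (1-based, inclusive, in the query), `score`, `f8_his`.
#' @export
scan_domains <- function(query, probe = mb_reference_sequence(),
                         min_score = 60, min_len = 90, max_len = 180,
                         probe_f8 = NULL) {
  q <- as_seq_record(query, "query")
  p <- as_seq_record(probe, "probe")
  check_aa_string(q$sequence, "query")
  check_aa_string(p$sequence, "probe")
  if (nchar(q$sequence) < nchar(p$sequence)) {
    abort_globinkit("query must be at least as long as the probe",
                    "globinkit_bad_input")
  }
  if (is.null(probe_f8)) {
    probe_f8 <- if (identical(p$sequence, mb_reference_sequence())) 93L else NA_integer_
  }
  mat <- blosum62_matrix()
  calls <- scan_segment(q$sequence, 1L, nchar(q$sequence), p$sequence,
                        mat, min_score, min_len, max_len, probe_f8)
  if (length(calls) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          score = numeric(), f8_his = logical()))
  }
  out <- dplyr::bind_rows(calls)
  dplyr::arrange(out, .data$start)
}

#' @noRd
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

# Recursively scan query[lo..hi]; accepted hits split the segment so calls
# can never overlap.
#' @noRd
scan_segment <- function(query, lo, hi, probe, mat, min_score,
                         min_len, max_len, probe_f8) {
  if (hi - lo + 1 < min_len) return(list())
  seg <- substr(query, lo, hi)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(probe),
    subject = Biostrings::AAString(seg),
    type = "local", substitutionMatrix = mat,
    gapOpening = 11, gapExtension = 1
  )
  sc <- Biostrings::score(pa)
  if (sc < min_score) return(list())
  s_start <- lo + Biostrings::start(Biostrings::subject(pa)) - 1L
  s_end <- lo + Biostrings::end(Biostrings::subject(pa)) - 1L
  span <- s_end - s_start + 1L
  hit <- NULL
  if (span >= min_len && span <= max_len) {
    f8 <- NA
    if (!is.na(probe_f8)) {
      f8 <- hit_has_f8_his(pa, probe_f8)
    }
    hit <- list(tibble::tibble(start = s_start, end = s_end,
                               score = sc, f8_his = f8))
  }
  c(hit,
    scan_segment(query, lo, s_start - 1L, probe, mat, min_score,
                 min_len, max_len, probe_f8),
    scan_segment(query, s_end + 1L, hi, probe, mat, min_score,
                 min_len, max_len, probe_f8))
}

# Does the local alignment place an His opposite probe position probe_f8?
#' @noRd
hit_has_f8_his <- function(pa, probe_f8) {
  p_aln <- chars(as.character(Biostrings::alignedPattern(pa)))
  s_aln <- chars(as.character(Biostrings::alignedSubject(pa)))
  p_pos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  for (k in seq_along(p_aln)) {
    if (p_aln[[k]] != "-") p_pos <- p_pos + 1L
    if (p_aln[[k]] != "-" && p_pos == probe_f8) {
      return(!is.na(s_aln[[k]]) && s_aln[[k]] == "H")
    }
  }
  FALSE
}

#' Split a query into its called domain segments
#'
#' @param query Query protein (see [scan_domains()]).
#' @param calls Domain-call tibble from [scan_domains()] (columns `start`,
#'   `end`).
#' @return A tibble of sequence records, ids suffixed `_d1`, `_d2`, ...;
#'   the concatenation of the extracted segments, in order, is a
#'   subsequence of the query.
#' @export
split_domains <- function(query, calls) {
  q <- as_seq_record(query, "query")
  if (nrow(calls) == 0) {
    return(tibble::tibble(id = character(), description = character(),
                          sequence = character()))
  }
  calls <- dplyr::arrange(calls, .data$start)
  if (any(calls$start > calls$end) ||
      any(utils::head(calls$end, -1) >= utils::tail(calls$start, -1))) {
    abort_globinkit("domain calls overlap or are malformed", "globinkit_bad_input")
  }
  tibble::tibble(
    id = paste0(q$id, "_d", seq_len(nrow(calls))),
    description = sprintf("residues %d-%d", calls$start, calls$end),
    sequence = substring(q$sequence, calls$start, calls$end)
  )
}
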