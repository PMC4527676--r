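#' Read protein sequences from FASTA text
#'
#' Parses FASTA-formatted text (via Biostrings) into a tibble of sequence
#' records. Sequences are uppercased on read; only the 20 standard one-letter
#' amino-acid codes plus `X` are accepted (gap characters are additionally
#' allowed when `allow_gaps = TRUE`, as used for gapped alignment rows).
#'
#' @param text A single string of FASTA text, a character vector of lines,
#'   or a path to a FASTA file.
#' @param allow_gaps Permit `-` and `.` characters (gapped alignment rows).
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @examples
#' read_fasta(">a my protein\nMVLS\n>b\nPEPTIDE")
#' @export
read_fasta <- function(text, allow_gaps = FALSE) {
  lines <- fasta_lines(text)
  if (length(lines) == 0 || !any(nzchar(trimws(lines)))) {
    abort_globinkit("empty FASTA input", "globinkit_empty_input")
  }
  if (!grepl("^>", lines[which(nzchar(trimws(lines)))[1]])) {
    abort_globinkit("FASTA input does not start with a '>' header", "globinkit_parse_error")
  }
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  set <- Biostrings::readBStringSet(tf, format = "fasta")
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort_globinkit(
      sprintf("empty record for header '%s'", ids[which(empty)[1]]),
      "globinkit_empty_record"
    )
  }
  allowed <- c(AA_STANDARD, "X", if (allow_gaps) GAP_CHARS)
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(chars(seqs[[i]])), allowed)
    if (length(bad) > 0) {
      abort_globinkit(
        sprintf("record '%s' contains invalid residue code(s): %s",
                ids[[i]], paste(bad, collapse = ", ")),
        "globinkit_invalid_residue"
      )
    }
  }
  tibble::tibble(id = ids, description = desc, sequence = unname(seqs))
}

#' Write sequence records as FASTA text
#'
#' @param records A tibble with `id`, `sequence` and optionally `description`
#'   columns (as returned by [read_fasta()]), or a named character vector.
#' @param width Line-wrap width for sequence lines.
#' @return A single FASTA string. `read_fasta(write_fasta(x))` is the
#'   identity on canonical records.
#' @export
write_fasta <- function(records, width = 60) {
  if (is.character(records)) {
    records <- tibble::tibble(id = names(records), description = "",
                              sequence = unname(records))
  }
  if (nrow(records) == 0) {
    abort_globinkit("no records to write", "globinkit_empty_input")
  }
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  body <- vapply(records$sequence, function(s) {
    n <- nchar(s)
    starts <- seq(1, n, by = width)
    paste(substring(s, starts, pmin(starts + width - 1, n)), collapse = "\n")
  }, character(1))
  paste0(paste0(">", hdr, "\n", body, collapse = "\n"), "\n")
}

#' @noRd
fasta_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && !grepl("^>", text) &&
      file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1) {
    return(strsplit(text, "\n", fixed = TRUE)[[1]])
  }
  text
}
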