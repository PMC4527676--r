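# Shared constants and small helpers.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y",
  MSE = "M"  # selenomethionine kept, mapped to Met
)

#' @noRd
abort_globinkit <- function(msg, class) {
  rlang::abort(msg, class = c(class, "globinkit_error"))
}

#' Split a sequence string into single characters
#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Is each character a gap?
#' @noRd
is_gap_char <- function(x) x %in% GAP_CHARS

#' Validate a 1-letter amino-acid code (20 standard + X)
#' @noRd
check_aa_string <- function(x, what = "sequence") {
  bad <- setdiff(unique(chars(x)), c(AA_STANDARD, "X"))
  if (length(bad) > 0) {
    abort_globinkit(
      sprintf("%s contains invalid residue code(s): %s",
              what, paste(bad, collapse = ", ")),
      "globinkit_invalid_residue"
    )
  }
  invisible(x)
}

#' Accept a sequence as a string, a one-row sequence tibble, or a named
#' element of one; returns list(id=, sequence=).
#' @noRd
as_seq_record <- function(x, default_id = "seq") {
  if (is.character(x) && length(x) == 1 && is.null(names(x))) {
    return(list(id = default_id, sequence = toupper(x)))
  }
  if (is.character(x) && length(x) == 1) {
    return(list(id = names(x), sequence = toupper(unname(x))))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1) {
      abort_globinkit("expected exactly one sequence record", "globinkit_bad_input")
    }
    return(list(id = x$id[[1]], sequence = toupper(x$sequence[[1]])))
  }
  if (is.list(x) && !is.null(x$sequence)) {
    return(list(id = x$id %||% default_id, sequence = toupper(x$sequence)))
  }
  abort_globinkit("cannot interpret input as a sequence record", "globinkit_bad_input")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
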