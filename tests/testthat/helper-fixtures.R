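# Fixtures built in code: tiny PDB texts, random traces and alignments,
# and the brute-force dRMSD oracle used throughout.

# Minimal PDB text from residue tuples: list(list(resno, aa3, x, y, z,
# altloc = "", occ = 1, chain = "A", type = "ATOM"), ...)
make_pdb_text <- function(residues, atom = "CA") {
  lines <- vapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    altloc <- r$altloc %||% " "
    occ <- r$occ %||% 1
    chain <- r$chain %||% "A"
    type <- r$type %||% "ATOM"
    sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            type, i, atom, altloc, r$aa3, chain, r$resno,
            r$x, r$y, r$z, occ, 0)
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A random coordinate trace with n residues
random_trace <- function(n, id = "rand", seed = 1) {
  set.seed(seed)
  coord_trace(id, "A", tibble::tibble(
    residue_number = seq_len(n),
    insertion_code = "",
    amino_acid = sample(c("A", "L", "V", "G", "K", "E"), n, replace = TRUE),
    x = cumsum(rnorm(n, 3, 0.5)),
    y = rnorm(n, 0, 2),
    z = rnorm(n, 0, 2)
  ))
}

# Identity alignment of several traces / same-length members
identity_alignment <- function(ids, n) {
  ords <- matrix(rep(seq_len(n), length(ids)), ncol = length(ids),
                 dimnames = list(NULL, ids))
  struct_alignment(ords)
}

# Brute-force (naive double loop) evaluation of the per-site dRMSD
# definition and its overall value; independent of the package's
# vectorised implementation.
drmsd_oracle <- function(DA, DB) {
  n <- nrow(DA)
  per <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      acc <- acc + (DA[i, j] - DB[i, j])^2
    }
    per[i] <- sqrt(acc / (n - 1))
  }
  ms <- mean(per^2)
  list(per_site = per, overall = sqrt(ms), mean_square = ms)
}

# Apply a rigid transform to a trace's coordinates
transform_trace <- function(trace, rigid, id = paste0(trace$structure_id, "_rt")) {
  xyz <- trace_xyz(trace)
  xyz <- sweep(xyz %*% t(rigid$rotation), 2, rigid$translation, "+")
  res <- trace$residues
  res$x <- xyz[, 1]; res$y <- xyz[, 2]; res$z <- xyz[, 3]
  coord_trace(id, trace$chain_id, res)
}

# Gapped two-row alignment object from row strings
rows_alignment <- function(...) {
  rows <- c(...)
  read_gapped_alignment(write_fasta(rows))
}

# Mb self-alignment (reference vs an identical candidate)
mb_self_alignment <- function(candidate_id = "candidate",
                              candidate = mb_reference_sequence()) {
  rows_alignment(stats::setNames(
    c(mb_reference_sequence(), candidate),
    c("spermwhale_Mb", candidate_id)
  ))
}
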