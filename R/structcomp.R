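# Superposition-free structural comparison: intramolecular C-alpha distance
# matrices, the per-site dRMSD statistic, profile averaging, and classical
# least-squares rigid-body superposition.

#' Intramolecular C-alpha distance matrix
#'
#' @param trace A [coord_trace()].
#' @return An object of class `intra_dist`: list with `structure_id` and the
#'   symmetric Euclidean distance matrix `d` (Angstrom) over the trace's
#'   residues.
#' @export
intra_distances <- function(trace) {
  stopifnot(inherits(trace, "coord_trace"))
  xyz <- trace_xyz(trace)
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- NULL
  structure(list(structure_id = trace$structure_id, d = d),
            class = "intra_dist")
}

#' @export
print.intra_dist <- function(x, ...) {
  cat(sprintf("<intra_dist> %s: %d x %d\n", x$structure_id,
              nrow(x$d), ncol(x$d)))
  invisible(x)
}

#' @noRd
as_intra_dist <- function(x) {
  if (inherits(x, "intra_dist")) return(x)
  if (inherits(x, "coord_trace")) return(intra_distances(x))
  abort_globinkit("expected a coord_trace or intra_dist", "globinkit_bad_input")
}

#' Per-site distance-matrix RMSD (dRMSD) profile for a structure pair
#'
#' For two structures A and B sharing an alignment, the per-site deviation
#' at aligned column i is
#' \deqn{dRMSD_i(A,B) = \sqrt{\frac{1}{n-1} \sum_j [d_{ij}(A) - d_{ij}(B)]^2}}
#' where \eqn{d_{ij}(\cdot)} are intramolecular C-alpha distances, the sum
#' runs over all n columns aligned in both structures (the j = i term
#' contributes zero), and n is the number of aligned residues. Columns
#' gapped in either structure are flagged as gaps. Because only
#' intramolecular distances enter, the statistic is invariant under rigid
#' motion of either structure and requires no superposition. The overall
#' value is the root of the mean of the squared per-site contributions
#' (`sqrt_overall = FALSE` reports the literal mean of squares instead).
#'
#' @param A,B [coord_trace()] or [intra_dist()] objects whose
#'   `structure_id`s name members of `aln`.
#' @param aln A [struct_alignment()] containing both structures.
#' @param sqrt_overall Apply the square root to the mean of squared per-site
#'   contributions (default).
#' @return An object of class `site_profile`: per-column values (`NA` at
#'   gaps) plus `n_aligned`, `overall_rmsd`, `mean_square`, the pair of ids,
#'   and the alignment's confidence track when present.
#' @export
per_site_drmsd <- function(A, B, aln, sqrt_overall = TRUE) {
  A <- as_intra_dist(A)
  B <- as_intra_dist(B)
  stopifnot(inherits(aln, "struct_alignment"))
  cols <- both_aligned(aln, A$structure_id, B$structure_id)
  n <- length(cols)
  if (n < 2) {
    abort_globinkit("insufficient aligned residues (need at least 2)",
                    "globinkit_bad_input")
  }
  ia <- aln$ordinals[cols, A$structure_id]
  ib <- aln$ordinals[cols, B$structure_id]
  if (max(ia) > nrow(A$d) || max(ib) > nrow(B$d)) {
    abort_globinkit("alignment ordinals exceed structure size", "globinkit_bad_input")
  }
  DA <- A$d[ia, ia, drop = FALSE]
  DB <- B$d[ib, ib, drop = FALSE]
  diff2 <- (DA - DB)^2
  per_site <- sqrt(rowSums(diff2) / (n - 1))
  values <- rep(NA_real_, n_columns(aln))
  values[cols] <- per_site
  mean_square <- mean(per_site^2)
  new_site_profile(
    values = values,
    pair = c(A$structure_id, B$structure_id),
    n_aligned = n,
    mean_square = mean_square,
    overall_rmsd = if (sqrt_overall) sqrt(mean_square) else mean_square,
    confidence = aln$confidence
  )
}

#' @noRd
new_site_profile <- function(values, pair, n_aligned, mean_square,
                             overall_rmsd, confidence = NULL,
                             helix_labels = NULL) {
  structure(
    list(values = values, pair = pair, n_aligned = n_aligned,
         mean_square = mean_square, overall_rmsd = overall_rmsd,
         confidence = confidence, helix_labels = helix_labels),
    class = "site_profile"
  )
}

#' @export
print.site_profile <- function(x, ...) {
  cat(sprintf("<site_profile> %s vs %s: %d columns, n_aligned = %d, overall = %.4f A\n",
              x$pair[[1]], x$pair[[2]], length(x$values), x$n_aligned,
              x$overall_rmsd))
  invisible(x)
}

#' Average two per-site profiles column-wise
#'
#' The mean of the two per-site values is taken in every column where both
#' profiles are non-gap; a gap in either yields a gap. The overall value
#' carried is the mean of the two overall values.
#'
#' @param p1,p2 `site_profile` objects over the same alignment columns.
#' @return A `site_profile`.
#' @export
average_profiles <- function(p1, p2) {
  stopifnot(inherits(p1, "site_profile"), inherits(p2, "site_profile"))
  if (length(p1$values) != length(p2$values)) {
    abort_globinkit("profiles have mismatched column counts", "globinkit_bad_input")
  }
  values <- ifelse(is.na(p1$values) | is.na(p2$values), NA_real_,
                   (p1$values + p2$values) / 2)
  new_site_profile(
    values = values,
    pair = c(paste(p1$pair, collapse = "+"), paste(p2$pair, collapse = "+")),
    n_aligned = sum(!is.na(values)),
    mean_square = mean(c(p1$mean_square, p2$mean_square)),
    overall_rmsd = mean(c(p1$overall_rmsd, p2$overall_rmsd)),
    confidence = p1$confidence %||% p2$confidence
  )
}

#' Least-squares rigid-body superposition of two traces
#'
#' Finds the proper rotation (determinant +1; reflections excluded) and
#' translation minimising the sum of squared C-alpha deviations over the
#' aligned residue pairs (Kabsch algorithm), and reports the coordinate
#' RMSD after fitting. B is mapped onto A.
#'
#' @param traceA,traceB [coord_trace()] objects named in `aln`.
#' @param aln A [struct_alignment()] containing both structures.
#' @return An object of class `superposition`: `rotation` (3x3, orthonormal,
#'   det +1), `translation` (length 3), `coordinate_rmsd` (Angstrom), and
#'   `transform_b` — a function mapping an n x 3 matrix of B coordinates
#'   into A's frame.
#' @export
superpose <- function(traceA, traceB, aln) {
  stopifnot(inherits(traceA, "coord_trace"), inherits(traceB, "coord_trace"))
  cols <- both_aligned(aln, traceA$structure_id, traceB$structure_id)
  if (length(cols) < 3) {
    abort_globinkit("need at least 3 aligned residue pairs", "globinkit_bad_input")
  }
  Pa <- trace_xyz(traceA)[aln$ordinals[cols, traceA$structure_id], , drop = FALSE]
  Pb <- trace_xyz(traceB)[aln$ordinals[cols, traceB$structure_id], , drop = FALSE]
  ca <- colMeans(Pa); cb <- colMeans(Pb)
  Xa <- sweep(Pa, 2, ca); Xb <- sweep(Pb, 2, cb)
  if (max(svd(Xa)$d) < 1e-12 || svd(Xa)$d[2] < 1e-12) {
    abort_globinkit("aligned points are collinear or degenerate", "globinkit_bad_input")
  }
  H <- t(Xb) %*% Xa
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  fitted <- Xb %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Xa)^2)))
  translation <- as.numeric(ca - cb %*% t(R))
  structure(
    list(rotation = R, translation = translation, coordinate_rmsd = rmsd,
         n_pairs = length(cols),
         transform_b = function(xyz) sweep(xyz %*% t(R), 2, translation, "+")),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d aligned pairs, coordinate RMSD %.4f A\n",
              x$n_pairs, x$coordinate_rmsd))
  invisible(x)
}

#' Structure-guided fallback alignment of C-alpha traces
#'
#' Builds a pairwise (or star, versus the first trace) alignment when no
#' external summary alignment is available: an initial residue
#' correspondence from a global sequence alignment seeds a least-squares
#' superposition, after which residues are re-paired as mutual nearest
#' C-alpha neighbours within `max_dist`, kept monotonic along both chains;
#' superposition and re-pairing are iterated. Intended as a stated-fallback
#' only — a proper joint structural aligner's summary alignment is the
#' preferred input for paper-grade comparisons.
#'
#' @param traces List of [coord_trace()] objects (first is the reference).
#' @param max_dist Pairing cutoff in Angstrom.
#' @param iterations Superpose/re-pair rounds.
#' @return A [struct_alignment()] whose columns follow the reference trace's
#'   residues (reference residues unpaired in any member remain columns with
#'   gaps in that member; non-reference residues outside any pairing are not
#'   represented).
#' @export
structure_guided_alignment <- function(traces, max_dist = 5, iterations = 3) {
  if (length(traces) < 2) {
    abort_globinkit("need at least 2 traces", "globinkit_bad_input")
  }
  ids <- vapply(traces, function(t) t$structure_id, character(1))
  if (anyDuplicated(ids)) {
    abort_globinkit("traces must have unique structure_ids", "globinkit_bad_input")
  }
  ref <- traces[[1]]
  n_ref <- length(ref)
  ords <- matrix(NA_integer_, nrow = n_ref, ncol = length(traces),
                 dimnames = list(NULL, ids))
  ords[, 1] <- seq_len(n_ref)
  for (k in 2:length(traces)) {
    pairs <- pair_traces(ref, traces[[k]], max_dist, iterations)
    ords[pairs$i, k] <- pairs$j
  }
  struct_alignment(ords)
}

#' @noRd
pair_traces <- function(ta, tb, max_dist, iterations) {
  # seed correspondence from a global sequence alignment
  mat <- blosum62_matrix()
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(trace_sequence(ta)),
    subject = Biostrings::AAString(trace_sequence(tb)),
    type = "global", substitutionMatrix = mat,
    gapOpening = 11, gapExtension = 1
  )
  sa <- chars(as.character(Biostrings::alignedPattern(pa)))
  sb <- chars(as.character(Biostrings::alignedSubject(pa)))
  ia <- cumsum(sa != "-"); ib <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  pairs <- list(i = ia[keep], j = ib[keep])
  Xa <- trace_xyz(ta); Xb <- trace_xyz(tb)
  for (it in seq_len(iterations)) {
    if (length(pairs$i) < 3) break
    fit <- kabsch_fit(Xa[pairs$i, , drop = FALSE], Xb[pairs$j, , drop = FALSE])
    Yb <- sweep(Xb %*% t(fit$R), 2, fit$t, "+")
    pairs <- mutual_nearest_monotonic(Xa, Yb, max_dist)
  }
  pairs
}

#' @noRd
kabsch_fit <- function(Pa, Pb) {
  ca <- colMeans(Pa); cb <- colMeans(Pb)
  H <- t(sweep(Pb, 2, cb)) %*% sweep(Pa, 2, ca)
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  list(R = R, t = as.numeric(ca - cb %*% t(R)))
}

# Mutual nearest neighbours within cutoff, filtered to a monotonic chain
# (longest increasing subsequence of partner indices).
#' @noRd
mutual_nearest_monotonic <- function(Xa, Yb, max_dist) {
  d2 <- outer(rowSums(Xa^2), rowSums(Yb^2), "+") - 2 * Xa %*% t(Yb)
  d2[d2 < 0] <- 0
  nn_a <- apply(d2, 1, which.min)
  nn_b <- apply(d2, 2, which.min)
  i <- which(nn_b[nn_a] == seq_len(nrow(Xa)) &
               d2[cbind(seq_len(nrow(Xa)), nn_a)] <= max_dist^2)
  j <- nn_a[i]
  keep <- lis_indices(j)
  list(i = i[keep], j = j[keep])
}

#' Longest strictly increasing subsequence (indices)
#' @noRd
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  best_len <- integer(n); prev <- integer(n)
  for (k in seq_len(n)) {
    cand <- which(x[seq_len(k - 1)] < x[k])
    if (length(cand) == 0) {
      best_len[k] <- 1L; prev[k] <- 0L
    } else {
      b <- cand[which.max(best_len[cand])]
      best_len[k] <- best_len[b] + 1L; prev[k] <- b
    }
  }
  k <- which.max(best_len)
  out <- integer(0)
  while (k > 0) { out <- c(k, out); k <- prev[k] }
  out
}
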