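# Distance phylogeny: p-distances with pairwise deletion, Poisson
# correction, neighbor joining, bootstrap support, majority-rule consensus.

#' Observed proportion of differing sites (p-distance)
#'
#' Computed with pairwise deletion: only columns where both rows carry a
#' standard residue (no gap, no `X`) are compared.
#'
#' @param a,b Gapped row strings of equal length.
#' @return Proportion in \eqn{[0, 1]}, or `NA` when no column is comparable.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort_globinkit("aligned rows differ in length", "globinkit_ragged_alignment")
  }
  ca <- chars(a); cb <- chars(b)
  ok <- ca %in% AA_STANDARD & cb %in% AA_STANDARD
  if (!any(ok)) return(NA_real_)
  mean(ca[ok] != cb[ok])
}

#' Poisson correction for superimposed substitutions
#'
#' \eqn{d = -\ln(1 - p)}: corrects the observed proportion of differing
#' sites for multiple hits under a Poisson substitution process.
#'
#' @param p Observed proportion(s) of differing sites, in \eqn{[0, 1)}.
#' @return Corrected distance(s).
#' @export
poisson_correct <- function(p) {
  if (any(!is.na(p) & (p < 0 | p >= 1))) {
    abort_globinkit("saturated distance: p must lie in [0, 1)",
                    "globinkit_saturated")
  }
  -log(1 - p)
}

#' Poisson-corrected distance matrix of a protein MSA
#'
#' @param msa MSA in any form accepted by [build_identity_matrix()].
#' @param correction `"poisson"` (default) or `"p"` for the raw proportion.
#' @return Symmetric distance matrix with ids as dimnames; `NA` marks pairs
#'   with no comparable columns or saturated (p = 1) comparisons.
#' @export
protein_distances <- function(msa, correction = c("poisson", "p")) {
  correction <- match.arg(correction)
  rows <- msa_rows(msa)
  n <- length(rows)
  m <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p <- p_distance(rows[[i]], rows[[j]])
        d <- if (is.na(p) || (correction == "poisson" && p >= 1)) {
          NA_real_
        } else if (correction == "poisson") {
          -log(1 - p)
        } else {
          p
        }
        m[i, j] <- m[j, i] <- d
      }
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with the Q-criterion; ties in the
#' Q minimisation are broken by the lowest index pair. Negative branch
#' lengths are clamped to zero; the total clamped deficit is recorded in
#' the `negative_branch_deficit` attribute of the returned tree. NJ is
#' exact on additive matrices.
#'
#' @param d Symmetric distance matrix with at least 3 taxa and ids as
#'   dimnames; no missing entries.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  ids <- rownames(d)
  n <- length(ids)
  if (is.null(ids)) {
    abort_globinkit("distance matrix must have ids as dimnames", "globinkit_bad_input")
  }
  if (n < 3) {
    abort_globinkit("need at least 3 taxa", "globinkit_bad_input")
  }
  na <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(na) > 0) {
    abort_globinkit(
      sprintf("missing distance for pair %s, %s",
              ids[na[1, 1]], ids[na[1, 2]]),
      "globinkit_missing_distance"
    )
  }
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + abs(x); 0 } else x
  }
  # each active node carries a newick fragment
  frag <- ids
  active <- seq_len(n)
  D <- d
  while (length(active) > 3) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    rs <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    # lowest index pair on ties: scan i<j in order
    best <- c(NA, NA); best_q <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (Q[i, j] < best_q - 1e-12) { best_q <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- 0.5 * Dm[i, j] + (rs[i] - rs[j]) / (2 * (m - 2))
    bj <- Dm[i, j] - bi
    bi <- clamp(bi); bj <- clamp(bj)
    u <- nrow(D) + 1L
    # distances from the new node to the remaining active nodes
    newd <- 0.5 * (Dm[i, ] + Dm[j, ] - Dm[i, j])
    D <- rbind(cbind(D, NA_real_), NA_real_)
    D[u, active] <- newd
    D[active, u] <- newd
    D[u, u] <- 0
    frag[u] <- sprintf("(%s:%s,%s:%s)",
                       frag[active[i]], fmt_bl(bi),
                       frag[active[j]], fmt_bl(bj))
    active <- c(active[-c(i, j)], u)
  }
  a <- active
  Dm <- D[a, a, drop = FALSE]
  b1 <- clamp((Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2)
  b2 <- clamp((Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2)
  b3 <- clamp((Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[a[1]], fmt_bl(b1), frag[a[2]], fmt_bl(b2),
                 frag[a[3]], fmt_bl(b3))
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_branch_deficit") <- deficit
  tree
}

#' @noRd
fmt_bl <- function(x) sprintf("%.12g", x)

#' Bootstrap support for the neighbor-joining tree of an MSA
#'
#' Builds the full-data NJ tree from Poisson-corrected distances, then
#' resamples alignment columns with replacement `replicates` times,
#' rebuilding the tree each time. Replicates whose resampled matrix has a
#' saturated (p = 1) or empty pairwise comparison are dropped and counted.
#' Support for each internal branch of the full-data tree is the percentage
#' of valid replicates containing that bipartition, attached as integer
#' node labels.
#'
#' @param msa MSA (at least 4 rows) in any form accepted by
#'   [build_identity_matrix()].
#' @param replicates Number of bootstrap replicates.
#' @param seed Seed for column resampling.
#' @return The full-data NJ tree with `node.label` support percentages;
#'   attribute `dropped_replicates` counts discarded replicates.
#' @export
bootstrap_support <- function(msa, replicates = 1000, seed = 1234) {
  rows <- msa_rows(msa)
  if (length(rows) < 4) {
    abort_globinkit("need at least 4 sequences", "globinkit_bad_input")
  }
  D <- protein_distances(rows)
  off <- D[upper.tri(D)]
  if (all(is.na(off)) || all(off[!is.na(off)] == 0)) {
    abort_globinkit("no variation among sequences", "globinkit_no_variation")
  }
  full <- nj_tree(D)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(mat) <- names(rows)
  L <- ncol(mat)
  set.seed(seed)
  trees <- list()
  dropped <- 0L
  for (r in seq_len(replicates)) {
    idx <- sample.int(L, L, replace = TRUE)
    sub <- apply(mat[, idx, drop = FALSE], 1, paste, collapse = "")
    Dr <- protein_distances(sub)
    if (any(is.na(Dr[upper.tri(Dr)]))) {
      dropped <- dropped + 1L
      next
    }
    trees[[length(trees) + 1]] <- nj_tree(Dr)
  }
  if (length(trees) == 0) {
    abort_globinkit("all bootstrap replicates were dropped", "globinkit_no_variation")
  }
  counts <- ape::prop.clades(full, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- as.character(round(100 * counts / length(trees)))
  attr(full, "dropped_replicates") <- dropped
  full
}

#' Majority-rule consensus of a set of trees
#'
#' Retains the bipartitions present in more than half of the input trees
#' (which are mutually compatible by construction) and labels each internal
#' branch with its frequency as an integer percentage.
#'
#' @param trees A list of [ape::phylo] trees (or `multiPhylo`) over the
#'   same leaf set.
#' @return An [ape::phylo] consensus tree with percentage `node.label`s.
#' @export
majority_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) {
    abort_globinkit("no trees given", "globinkit_empty_input")
  }
  cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.label <- as.character(round(100 * counts / length(trees)))
  cons
}
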