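# Seed-deterministic generators: protein families evolved on a known tree,
# helical-bundle coordinate templates, perturbed structures with ground-truth
# alignments, and tandem multidomain constructions.

#' Configuration for simulating a protein family on a tree
#'
#' @param tree An [ape::phylo] tree with branch lengths in expected
#'   substitutions per site, or Newick text.
#' @param n_sites Number of independently evolving sites.
#' @param seed Integer seed; identical configs give byte-identical output.
#' @param root_composition Length-20 probability vector over the standard
#'   amino acids (alphabetical order); default uniform.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(tree, n_sites, seed = 1,
                              root_composition = rep(1 / 20, 20)) {
  if (is.character(tree)) tree <- read_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort_globinkit("tree must have non-negative branch lengths", "globinkit_bad_input")
  }
  if (n_sites < 1) {
    abort_globinkit("n_sites must be at least 1", "globinkit_bad_input")
  }
  if (length(root_composition) != 20 ||
      abs(sum(root_composition) - 1) > 1e-8 || any(root_composition < 0)) {
    abort_globinkit("root_composition must be 20 non-negative values summing to 1",
                    "globinkit_bad_input")
  }
  structure(list(tree = tree, n_sites = as.integer(n_sites),
                 seed = as.integer(seed), root_composition = root_composition),
            class = "simulation_config")
}

#' Simulate a protein family on a known tree
#'
#' Sites evolve independently under a Poisson substitution process: along a
#' branch of length b the number of substitutions at a site is Poisson(b),
#' and each substitution replaces the residue with one of the other 19
#' amino acids chosen uniformly. This is exactly the regime assumed by the
#' Poisson distance correction, so simulated families close the loop for
#' the neighbor-joining stage.
#'
#' @param config A [simulation_config()].
#' @return List with `alignment` (named character vector of ungapped leaf
#'   sequences, one per tip, equal length — a trivially aligned MSA) and
#'   `tree` (the generating tree).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- ape::reorder.phylo(config$tree, "cladewise")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  set.seed(config$seed)
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample.int(20, config$n_sites, replace = TRUE,
                             prob = config$root_composition)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    b <- tree$edge.length[e]
    s <- seqs[[parent]]
    k <- stats::rpois(config$n_sites, b)
    if (any(k > 0)) {
      for (step in seq_len(max(k))) {
        idx <- which(k >= step)
        # uniform jump to one of the 19 other residues
        s[idx] <- ((s[idx] - 1L +
                      sample.int(19, length(idx), replace = TRUE)) %% 20L) + 1L
      }
    }
    seqs[[child]] <- s
  }
  aln <- vapply(seq_len(n_tip), function(i) {
    paste(AA_STANDARD[seqs[[i]]], collapse = "")
  }, character(1))
  names(aln) <- tree$tip.label
  list(alignment = aln, tree = config$tree)
}

#' Idealised alpha-helical bundle C-alpha template
#'
#' Builds a deterministic C-alpha trace of `n_helices` ideal alpha helices
#' (rise 1.5 A per residue, 100 degrees per residue about the helix axis,
#' C-alpha radius 2.3 A — successive C-alpha distances come out near 3.8 A)
#' packed antiparallel on a circular bundle layout.
#'
#' @param n_helices Number of helices.
#' @param residues_per_helix Residues in each helix.
#' @param bundle_radius Distance of each helix axis from the bundle centre (A).
#' @return A [coord_trace()] with `structure_id = "helical_template"`.
#' @export
make_helical_template <- function(n_helices = 8, residues_per_helix = 19,
                                  bundle_radius = 8) {
  rise <- 1.5; turn <- 100 * pi / 180; r_ca <- 2.3
  aa_cycle <- c("L", "A", "V", "E", "I", "K", "F", "D", "M", "S")
  res <- list()
  num <- 0L
  for (h in seq_len(n_helices)) {
    ang <- 2 * pi * (h - 1) / n_helices
    cx <- bundle_radius * cos(ang); cy <- bundle_radius * sin(ang)
    dir <- if (h %% 2 == 1) 1 else -1
    i <- seq_len(residues_per_helix)
    res[[h]] <- tibble::tibble(
      residue_number = num + i,
      insertion_code = "",
      amino_acid = aa_cycle[((num + i - 1) %% length(aa_cycle)) + 1],
      x = cx + r_ca * cos((i - 1) * turn),
      y = cy + r_ca * sin((i - 1) * turn),
      z = dir * (i - 1) * rise
    )
    num <- num + residues_per_helix
  }
  coord_trace("helical_template", "A", dplyr::bind_rows(res))
}

#' Configuration for perturbing a coordinate template
#'
#' @param template A [coord_trace()] to perturb.
#' @param per_site_sigma Isotropic Gaussian noise s.d. in Angstrom; scalar
#'   or one value per template residue.
#' @param rigid Optional rigid transform: list with `rotation` (3x3 proper
#'   rotation) and `translation` (length 3), e.g. from
#'   [random_rigid_transform()].
#' @param deletion_spans Optional list of integer vectors / ranges of
#'   template residue indices to delete (emulating e.g. a disordered helix).
#' @param seed Integer seed.
#' @return A list of class `perturb_config`.
#' @export
structure_perturb_config <- function(template, per_site_sigma = 0,
                                     rigid = NULL, deletion_spans = NULL,
                                     seed = 1) {
  stopifnot(inherits(template, "coord_trace"))
  n <- length(template)
  if (!length(per_site_sigma) %in% c(1L, n) || any(!is.finite(per_site_sigma)) ||
      any(per_site_sigma < 0)) {
    abort_globinkit("per_site_sigma must be finite, non-negative, scalar or per-residue",
                    "globinkit_bad_input")
  }
  if (!is.null(deletion_spans)) {
    del <- sort(unique(unlist(deletion_spans)))
    if (any(del < 1 | del > n)) {
      abort_globinkit("deletion spans must lie within the template", "globinkit_bad_input")
    }
  }
  structure(list(template = template, per_site_sigma = per_site_sigma,
                 rigid = rigid, deletion_spans = deletion_spans,
                 seed = as.integer(seed)),
            class = "perturb_config")
}

#' Random proper rigid transform
#'
#' @param seed Integer seed.
#' @param max_translation Translations drawn uniformly in
#'   `[-max_translation, max_translation]` per axis.
#' @return List with `rotation` (3x3, det +1) and `translation` (length 3).
#' @export
random_rigid_transform <- function(seed = 1, max_translation = 20) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R,
       translation = stats::runif(3, -max_translation, max_translation))
}

#' Perturb a coordinate template with known ground truth
#'
#' Adds isotropic Gaussian noise per retained residue, applies an optional
#' rigid transform, removes the requested deletion spans, and emits the
#' ground-truth column mapping back to the template.
#'
#' @param config A [structure_perturb_config()].
#' @param structure_id Id given to the perturbed trace.
#' @return List with `trace` (the perturbed [coord_trace()]) and
#'   `alignment` (a [struct_alignment()] of template and perturbed trace,
#'   one column per template residue, gaps over deleted spans).
#' @export
perturb_structure <- function(config, structure_id = "perturbed") {
  stopifnot(inherits(config, "perturb_config"))
  tmpl <- config$template
  n <- length(tmpl)
  del <- integer(0)
  if (!is.null(config$deletion_spans)) {
    del <- sort(unique(unlist(config$deletion_spans)))
  }
  keep <- setdiff(seq_len(n), del)
  set.seed(config$seed)
  sigma <- rep(config$per_site_sigma, length.out = n)[keep]
  xyz <- trace_xyz(tmpl)[keep, , drop = FALSE]
  xyz <- xyz + matrix(stats::rnorm(3 * length(keep), sd = rep(sigma, 3)),
                      ncol = 3)
  if (!is.null(config$rigid)) {
    xyz <- sweep(xyz %*% t(config$rigid$rotation), 2,
                 config$rigid$translation, "+")
  }
  residues <- tmpl$residues[keep, ]
  residues$x <- xyz[, 1]; residues$y <- xyz[, 2]; residues$z <- xyz[, 3]
  residues$residue_number <- seq_along(keep)
  trace <- coord_trace(structure_id, "A", residues)
  ords <- matrix(NA_integer_, nrow = n, ncol = 2,
                 dimnames = list(NULL, c(tmpl$structure_id, structure_id)))
  ords[, 1] <- seq_len(n)
  ords[keep, 2] <- seq_along(keep)
  list(trace = trace, alignment = struct_alignment(ords))
}

#' Construct a tandem multidomain protein with known intervals
#'
#' Concatenates `k` independently mutated copies of a single-domain
#' sequence joined by low-complexity linkers, emulating covalently linked
#' tandem globin repeats, and returns the planted domain intervals.
#'
#' @param domain Single-domain sequence (string, named vector, or one-row
#'   tibble).
#' @param k Number of tandem copies.
#' @param linker_len Linker length between consecutive copies.
#' @param mutation_rate Per-site probability that a copy position is
#'   replaced by one of the other 19 residues (uniformly).
#' @param seed Integer seed.
#' @return List with `record` (tibble: `id`, `description`, `sequence`) and
#'   `intervals` (tibble: `domain`, `start`, `end`, 1-based inclusive).
#' @export
make_multidomain <- function(domain, k, linker_len = 8, mutation_rate = 0,
                             seed = 1) {
  d <- as_seq_record(domain, "domain")
  check_aa_string(d$sequence, "domain")
  if (k < 1) abort_globinkit("k must be at least 1", "globinkit_bad_input")
  if (mutation_rate < 0 || mutation_rate >= 1) {
    abort_globinkit("mutation_rate must lie in [0, 1)", "globinkit_bad_input")
  }
  set.seed(seed)
  L <- nchar(d$sequence)
  base <- match(chars(d$sequence), AA_STANDARD)
  pieces <- character(0)
  starts <- integer(k); ends <- integer(k)
  pos <- 0L
  for (i in seq_len(k)) {
    s <- base
    hit <- which(stats::runif(L) < mutation_rate & !is.na(s))
    if (length(hit) > 0) {
      s[hit] <- ((s[hit] - 1L + sample.int(19, length(hit), replace = TRUE)) %% 20L) + 1L
    }
    copy <- chars(d$sequence)
    copy[!is.na(s)] <- AA_STANDARD[s[!is.na(s)]]
    copy <- paste(copy, collapse = "")
    starts[i] <- pos + 1L
    ends[i] <- pos + L
    pieces <- c(pieces, copy)
    pos <- pos + L
    if (i < k && linker_len > 0) {
      linker <- paste(sample(c("G", "S", "P"), linker_len, replace = TRUE),
                      collapse = "")
      pieces <- c(pieces, linker)
      pos <- pos + linker_len
    }
  }
  list(
    record = tibble::tibble(
      id = sprintf("%s_x%d", d$id, k),
      description = sprintf("%d tandem copies, linker %d, mutation rate %g",
                            k, linker_len, mutation_rate),
      sequence = paste(pieces, collapse = "")
    ),
    intervals = tibble::tibble(domain = seq_len(k), start = starts, end = ends)
  )
}

#' Canonical 8-taxon simulation tree
#'
#' The fixed 8-taxon tree used as the default study condition for family
#' simulation and topology-recovery checks: branch lengths span
#' 0.05-0.3 expected substitutions per site, the divergence regime typical
#' of globin subfamilies.
#'
#' @return An [ape::phylo] tree with 8 tips (`A`-`H`).
#' @export
default_family_tree <- function() {
  read_newick(paste0(
    "((A:0.1,B:0.15):0.08,((C:0.12,D:0.2):0.1,",
    "((E:0.15,F:0.1):0.07,(G:0.25,H:0.3):0.05):0.09):0.05);"
  ))
}
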