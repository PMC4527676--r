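# Intra-structure distance matrices, per-site dRMSD, profile averaging,
# and rigid-body superposition.

test_that("intra-distance matrices are symmetric Euclidean distances", {
  tr <- coord_trace("lin", "A", tibble::tibble(
    residue_number = 1:3, insertion_code = "",
    amino_acid = c("A", "A", "A"),
    x = c(0, 3.8, 7.6), y = 0, z = 0
  ))
  D <- intra_distances(tr)
  expect_equal(D$d[1, 2], 3.8)
  expect_equal(D$d[1, 3], 7.6)
  expect_equal(D$d, t(D$d))
  expect_equal(diag(D$d), rep(0, 3))

  single <- coord_trace("one", "A", tibble::tibble(
    residue_number = 1L, insertion_code = "", amino_acid = "A",
    x = 0, y = 0, z = 0))
  expect_equal(intra_distances(single)$d, matrix(0, 1, 1))
})

test_that("per-site dRMSD reproduces the hand-worked 3-residue example", {
  # A: d12 = 3.8, d13 = 7.6, d23 = 3.8 (collinear); B: d13 shrinks to 5.0
  A <- structure(list(structure_id = "A",
                      d = rbind(c(0, 3.8, 7.6), c(3.8, 0, 3.8), c(7.6, 3.8, 0))),
                 class = "intra_dist")
  B <- structure(list(structure_id = "B",
                      d = rbind(c(0, 3.8, 5.0), c(3.8, 0, 3.8), c(5.0, 3.8, 0))),
                 class = "intra_dist")
  aln <- identity_alignment(c("A", "B"), 3)
  prof <- per_site_drmsd(A, B, aln)
  expected_site <- sqrt(2.6^2 / 2)           # 1.8385 at sites 1 and 3
  expected_overall <- sqrt(mean(c(2.6^2 / 2, 0, 2.6^2 / 2)))  # 1.5011
  expect_equal(prof$values, c(expected_site, 0, expected_site), tolerance = 1e-12)
  expect_equal(round(prof$values[1], 4), 1.8385)
  expect_equal(prof$overall_rmsd, expected_overall, tolerance = 1e-12)
  expect_equal(round(prof$overall_rmsd, 4), 1.5011)
  expect_equal(prof$n_aligned, 3)

  oracle <- drmsd_oracle(A$d, B$d)
  expect_equal(prof$values, oracle$per_site, tolerance = 1e-12)
  expect_equal(prof$overall_rmsd, oracle$overall, tolerance = 1e-12)

  # literal mean-of-squares reading
  prof_ms <- per_site_drmsd(A, B, aln, sqrt_overall = FALSE)
  expect_equal(prof_ms$overall_rmsd, oracle$mean_square, tolerance = 1e-12)
})

test_that("vectorised dRMSD matches the naive double-loop oracle on random fixtures", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:15, 1)
    ta <- random_trace(n, "A", seed)
    tb <- random_trace(n, "B", seed + 100)
    aln <- identity_alignment(c("A", "B"), n)
    prof <- per_site_drmsd(ta, tb, aln)
    oracle <- drmsd_oracle(intra_distances(ta)$d, intra_distances(tb)$d)
    expect_equal(prof$values, oracle$per_site, tolerance = 1e-12)
    expect_equal(prof$overall_rmsd, oracle$overall, tolerance = 1e-12)
  }
})

test_that("dRMSD is symmetric in its arguments and zero iff matrices agree", {
  ta <- random_trace(12, "A", 7)
  tb <- random_trace(12, "B", 8)
  aln <- identity_alignment(c("A", "B"), 12)
  pab <- per_site_drmsd(ta, tb, aln)
  pba <- per_site_drmsd(tb, ta, aln)
  expect_identical(pab$values, pba$values)
  expect_identical(pab$overall_rmsd, pba$overall_rmsd)

  self <- per_site_drmsd(ta, transform_trace(ta, random_rigid_transform(3), "B"),
                         aln)
  expect_true(all(self$values < 1e-9))
  expect_lt(self$overall_rmsd, 1e-9)
  expect_gt(pab$overall_rmsd, 0)
})

test_that("gap columns are flagged and excluded from the aligned count", {
  ta <- random_trace(10, "A", 1)
  tb <- random_trace(8, "B", 2)
  ords <- cbind(A = 1:10, B = c(1:4, NA, 5:8, NA))
  aln <- struct_alignment(ords)
  expect_equal(aligned_length(aln, "A", "B"), 8)
  prof <- per_site_drmsd(ta, tb, aln)
  expect_true(all(is.na(prof$values[c(5, 10)])))
  expect_equal(sum(!is.na(prof$values)), 8)
  expect_equal(prof$n_aligned, 8)

  expect_error(per_site_drmsd(ta, tb, struct_alignment(
    cbind(A = c(1L, NA), B = c(NA, 1L)))), "insufficient aligned")
})

test_that("profile averaging is column-wise with gap propagation", {
  mk <- function(v, pair) {
    structure(list(values = v, pair = pair, n_aligned = sum(!is.na(v)),
                   mean_square = mean(v^2, na.rm = TRUE),
                   overall_rmsd = sqrt(mean(v^2, na.rm = TRUE)),
                   confidence = NULL, helix_labels = NULL),
              class = "site_profile")
  }
  p1 <- mk(c(0, 2, 1), c("A", "T"))
  p2 <- mk(c(2, 0, NA), c("B", "T"))
  avg <- average_profiles(p1, p2)
  expect_equal(avg$values, c(1, 1, NA))
  expect_equal(avg$overall_rmsd, mean(c(p1$overall_rmsd, p2$overall_rmsd)))
  expect_identical(average_profiles(p1, p1)$values, p1$values)
  expect_error(average_profiles(p1, mk(c(0, 1), c("C", "T"))), "mismatched")
})

test_that("superposition recovers known rigid motions", {
  ta <- random_trace(50, "A", 11)
  aln <- identity_alignment(c("A", "B"), 50)

  # identical point sets
  tb0 <- transform_trace(ta, list(rotation = diag(3), translation = c(0, 0, 0)), "B")
  s0 <- superpose(ta, tb0, aln)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  expect_lt(s0$coordinate_rmsd, 1e-9)

  # known rotation recovered
  rt <- random_rigid_transform(5)
  tb <- transform_trace(ta, rt, "B")
  s <- superpose(ta, tb, aln)
  expect_lt(s$coordinate_rmsd, 1e-9)
  expect_equal(s$rotation %*% rt$rotation, diag(3), tolerance = 1e-6)
  expect_equal(t(s$rotation) %*% s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  # applying the fit maps B onto A
  expect_lt(max(abs(s$transform_b(trace_xyz(tb)) - trace_xyz(ta))), 1e-6)

  expect_error(superpose(ta, tb, struct_alignment(
    cbind(A = c(1L, 2L, NA), B = c(1L, 2L, NA)))), "at least 3")
})

test_that("fitted coordinate RMSD for noisy copies sits in the Monte-Carlo band", {
  rmsds <- vapply(1:20, function(seed) {
    set.seed(seed)
    ta <- random_trace(100, "A", seed)
    res <- ta$residues
    res$x <- res$x + rnorm(100, sd = 0.5)
    res$y <- res$y + rnorm(100, sd = 0.5)
    res$z <- res$z + rnorm(100, sd = 0.5)
    tb <- coord_trace("B", "A", res)
    superpose(ta, tb, identity_alignment(c("A", "B"), 100))$coordinate_rmsd
  }, numeric(1))
  expect_true(all(rmsds >= 0.6 & rmsds <= 1.1))
})

test_that("superposition never increases RMSD over the raw overlay", {
  for (seed in 1:5) {
    ta <- random_trace(30, "A", seed)
    tb <- random_trace(30, "B", seed + 50)
    aln <- identity_alignment(c("A", "B"), 30)
    raw <- sqrt(mean(rowSums((trace_xyz(ta) - trace_xyz(tb))^2)))
    expect_lte(superpose(ta, tb, aln)$coordinate_rmsd, raw + 1e-12)
  }
})

test_that("structure-guided fallback alignment recovers ground truth on a perturbed bundle", {
  tmpl <- make_helical_template()
  pert <- perturb_structure(structure_perturb_config(
    tmpl, per_site_sigma = 0.3, rigid = random_rigid_transform(9),
    deletion_spans = list(39:57), seed = 4))
  aln <- structure_guided_alignment(list(tmpl, pert$trace))
  truth <- pert$alignment
  n <- aligned_length(truth, "helical_template", "perturbed")
  got <- aligned_length(aln, "helical_template", "perturbed")
  expect_gte(got, round(0.9 * n))
  # pairs present must agree with the construction mapping
  cols <- which(!is.na(aln$ordinals[, "perturbed"]))
  expect_true(all(
    truth$ordinals[aln$ordinals[cols, "helical_template"], "perturbed"] ==
      aln$ordinals[cols, "perturbed"], na.rm = TRUE
  ))
})
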