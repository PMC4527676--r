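# Myoglobin-fold template checks and helix-relative intron notation.

test_that("the myoglobin reference passes its own fold check", {
  res <- check_mb_fold(mb_self_alignment())
  expect_true(res$verdict)
  expect_true(res$f8_his)
  expect_true(all(c("B", "C", "E", "F", "G") %in% res$helices_present))
  expect_gte(res$hydrophobic_fraction, 0.70)
  # template positions all resolved, none gapped
  expect_equal(sum(is.na(tidy(res)$residue)), 0)
  expect_equal(nrow(tidy(res)), 36)
  # variant template carries 37 positions
  res37 <- check_mb_fold(mb_self_alignment(), template = mb_fold_template("s1fig"))
  expect_equal(nrow(tidy(res37)), 37)
  expect_true(res37$verdict)
})

test_that("mutating the proximal F8 His fails the check", {
  cand <- mb_reference_sequence()
  substr(cand, 93, 93) <- "A"
  res <- check_mb_fold(mb_self_alignment(candidate = cand))
  expect_false(res$f8_his)
  expect_false(res$verdict)
})

test_that("a candidate missing helices G and H is called defective", {
  cand <- mb_reference_sequence()
  # delete everything from helix G onward (residues 100-153)
  cand_row <- paste0(substr(cand, 1, 99), strrep("-", 153 - 99))
  aln <- rows_alignment(c(spermwhale_Mb = mb_reference_sequence(),
                          truncated = cand_row))
  res <- check_mb_fold(aln)
  expect_false("G" %in% res$helices_present)
  expect_false("H" %in% res$helices_present)
  expect_false(res$verdict)
  expect_true(res$f8_his)  # F8 still intact; the helix rule alone fails it
})

test_that("fold verdict is invariant under all-gap columns and monotone in helix loss", {
  base <- mb_self_alignment()
  # splice three all-gap columns into both rows
  rows <- vapply(base$rows, function(r) {
    paste0(substr(r, 1, 50), "---", substr(r, 51, nchar(r)))
  }, character(1))
  # all-gap columns make read_gapped_alignment rows identical in length
  aln2 <- rows_alignment(rows)
  expect_identical(glance(check_mb_fold(aln2))[-1],
                   glance(check_mb_fold(base))[-1])

  # removing any single required helix never flips fail -> pass
  ann <- mb_helix_annotation()
  for (h in c("B", "C", "E", "F", "G")) {
    span <- range(ann$residue_number[ann$segment == h])
    cand <- chars(mb_reference_sequence())
    cand[span[1]:span[2]] <- "-"
    aln_h <- rows_alignment(c(spermwhale_Mb = mb_reference_sequence(),
                              cand = paste(cand, collapse = "")))
    expect_false(check_mb_fold(aln_h)$verdict)
  }
})

test_that("externally supplied Z-scores gate the verdict; strict mode drops hydrophobicity", {
  aln <- mb_self_alignment()
  expect_true(check_mb_fold(aln, fugue_z = 12)$verdict)
  expect_false(check_mb_fold(aln, fugue_z = 4.2)$verdict)
  expect_equal(glance(check_mb_fold(aln, fugue_z = 12))$fugue_z, 12)

  # a hydrophilic-at-template-positions mutant: passes only in strict mode
  cand <- chars(mb_reference_sequence())
  ann <- mb_helix_annotation()
  tpl <- mb_fold_template()
  hp <- tpl$positions$label[tpl$positions$role != "F8_his"]
  cand[ann$residue_number[ann$label %in% hp]] <- "K"
  row <- paste(cand, collapse = "")
  aln_k <- rows_alignment(c(spermwhale_Mb = mb_reference_sequence(), mut = row))
  expect_false(check_mb_fold(aln_k)$verdict)
  expect_true(check_mb_fold(aln_k, strict = TRUE)$verdict)
})

test_that("hydrophobicity classification follows the template set", {
  expect_true(classify_hydrophobic("L"))
  expect_false(classify_hydrophobic("K"))
  expect_false(classify_hydrophobic("X"))
  expect_error(classify_hydrophobic("B"), "invalid residue")
})

test_that("intron offsets map to the quoted helix-relative notations", {
  aln <- mb_self_alignment()
  ann <- mb_helix_annotation()
  # B12 is reference residue 31: intron after nt 2 of its codon -> B12.2
  b12 <- ann$residue_number[ann$label == "B12"]
  expect_equal(map_intron_position(3 * (b12 - 1) + 2, aln), "B12.2")
  # G7 is residue 106: intron exactly between codons of G6 and G7 -> G7.0
  g7 <- ann$residue_number[ann$label == "G7"]
  expect_equal(map_intron_position(3 * (g7 - 1), aln), "G7.0")
  # 1 nt into codon 1 of the chain start (pre-A here)
  expect_equal(map_intron_position(1, aln), "pre-A.1")
  expect_error(map_intron_position(0, aln), "must lie in")
  expect_error(map_intron_position(3 * 153, aln), "must lie in")
})

test_that("intron phase arithmetic is exact for every offset of a toy helix", {
  # candidate = reference: walk all offsets across helix B and check the
  # notation against direct (residue, phase) enumeration
  aln <- mb_self_alignment()
  ann <- mb_helix_annotation()
  b <- ann[ann$segment == "B", ]
  for (idx in b$index) {
    res <- b$residue_number[b$index == idx]
    for (phase in 0:2) {
      off <- if (phase == 0) 3 * (res - 1) else 3 * (res - 1) + phase
      expect_equal(map_intron_position(off, aln),
                   sprintf("B%d.%d", idx, phase))
    }
  }
})

test_that("an incomplete reference annotation is reported", {
  short_ref <- substr(mb_reference_sequence(), 1, 120)
  aln <- rows_alignment(c(spermwhale_Mb = paste0(short_ref, strrep("-", 33)),
                          cand = mb_reference_sequence()))
  # reference lacks helix H residues entirely -> H-template labels unresolvable
  expect_error(check_mb_fold(aln), "annotation incomplete")
})
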