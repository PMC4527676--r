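---
title: "Methods: fold validation, distance-matrix RMSD, and distance phylogenetics in globinkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fold validation, distance-matrix RMSD, and distance phylogenetics in globinkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globinkit)
```

This vignette is the package's own account of the models and procedures it
implements, the choices that were genuinely open, and what its tests do and
do not establish.

## The myoglobin-fold check

All known globins share the 3/3 α-helical myoglobin fold: a pattern of
predominantly hydrophobic residues at roughly 36 conserved,
solvent-inaccessible helix positions, plus an invariant proximal histidine
at position F8 that ligates the heme iron. `check_mb_fold()` operationalises
this as follows. The candidate is aligned to an annotated reference — the
shipped 153-residue sperm whale myoglobin, with helices A–H and the
interhelical segments (AB, CD, …, GH) assigned to reference residue numbers
(distal His at E7 = residue 64, proximal His at F8 = residue 93, CD1 =
Phe43). Each template label is resolved through the reference to an
alignment column and thence to the candidate residue or a gap.

The verdict requires:

1. **F8 His** — a histidine in the candidate at the F8 column.
2. **Helix coverage** — the published criterion asks for "helices B through
   G". We read this as: at least half of the template positions of each of
   helices B, C, E, F and G carry a candidate residue. Helix D is
   deliberately excluded: the template assigns it no positions, and helix D
   is genuinely missing in some true globins (it is disordered in one of
   the sea cucumber coelomic hemoglobin structures), so requiring it would
   fail known globins. The 50% level makes single-column helices (helix C
   has one template position) behave sensibly while tolerating ragged helix
   ends.
3. **Hydrophobicity** — the fraction of occupied non-F8 template positions
   that are hydrophobic must reach `min_hydrophobic_fraction` (default
   0.70, reflecting "predominantly"; the hydrophobic set defaults to
   {A, C, F, I, L, M, V, W, Y} and both are configurable). The criteria
   sentence in the literature names only the Z-score, F8 and the helices,
   while the fold definition itself is the hydrophobic pattern; since both
   readings are defensible, both are provided — `strict = TRUE` enforces
   only rule 1–2 (and 4 when applicable).
4. **Z-score gate** — a structure-profile Z-score is accepted as *input
   metadata only* (`fugue_z`), never computed; when present, passing
   additionally requires `Z > 6`. Profile scanning itself is out of scope
   for this package.

Two template variants are shipped: the default 36-position list (C4, CD1,
FG4) and a 37-position variant (C5, adds CD4) that circulates alongside it;
they differ only in those columns and are selected by the `variant`
argument.

Note a behaviour the workflow tests document: when a long *random* sequence
is first aligned to the reference by a similarity-maximising aligner, the
aligner tends to place histidines opposite histidines and hydrophobics
opposite template positions, so the sequence-only rule can accept
non-globins. This is precisely why the published pipeline pairs the
template rule with a structure-profile Z-score; users screening unaligned
candidates should supply one.

**Intron notation.** `map_intron_position()` converts a coding-nucleotide
offset to helix-relative notation. With `phase = offset mod 3` and residue
`offset div 3 + 1`, phase 0 denotes an intron exactly between codons (the
downstream residue is named: an intron between the codons of helix-G
residues 6 and 7 is `G7.0`), and phases 1–2 fall inside the named codon
(`B12.2` is between positions 2 and 3 of the codon of helix-B residue 12).
The phase arithmetic is verified exhaustively over every offset of a helix
in the tests. Offsets mapping outside annotated helices return the
flanking-segment label (`pre-A`, interhelical segments, `post-H`);
insertions relative to the reference are attributed to the nearest
preceding aligned reference residue's segment.

## Tandem domain scanning

Chimeric globins with up to 14 covalently linked globin domains occur in
nature; published analyses presume the domain boundaries. The scan here is
deliberately simple and fully specified: Smith–Waterman local alignment of
a single-domain probe (default: the myoglobin reference) against the query
with BLOSUM62 and affine gaps (open 11, extend 1 — the standard protein
defaults), accept the best hit if its score reaches `min_score` (default
60), then split the query around the hit and rescan both flanks. Splitting
(rather than masking residues in place) guarantees calls can never overlap
and makes the procedure deterministic. Calls are trimmed to the
probe-covered span and must fall in `[min_len, max_len]` = [90, 180]
residues, bracketing the 110–160-residue range of real globin domains.
`min_score = 60` sits far below the score of a true domain at 20%
mutational load (hundreds) and far above chance hits of linker sequence,
so the exact value is uncritical; recovery of planted constructions with
k ∈ {1, 2, 5, 14} copies at 20% point mutation is part of the acceptance
suite.

## Redundancy reduction

Percent identity is `100 × identical / comparable`, where comparable
columns are those in which *both* rows carry a residue; `X` never matches.
Whether the reference web tool used this denominator or full alignment
length is not documented, so both are implemented
(`denominator = "comparable"` is the default; `"alignment"` is the other
reading). Reduction is the greedy Hobohm-1 sweep in input order: keep a
sequence iff its identity to every previously kept sequence is strictly
below the threshold. Input-order greed is deterministic and reproduces the
published behaviour up to the (undocumented) tie-handling of the original
tool. Missing pairwise values are treated as 0% so that incomparability
never forces removal. The tests verify the two defining invariants on
random matrices: maximality (every removed sequence is ≥ threshold to some
kept one) and monotonicity (raising the threshold never shrinks the kept
set).

## Distance-matrix RMSD (dRMSD)

For structures A and B sharing an alignment with n aligned residues,

$$\mathrm{dRMSD}_i(A,B) \;=\; \sqrt{\tfrac{1}{n-1}\sum_j \left[d_{ij}(A)-d_{ij}(B)\right]^2},$$

with $d_{ij}$ the intramolecular Cα–Cα distances and the sum over all
aligned columns $j$. The $j=i$ term is included — it contributes exactly
zero since $d_{ii}=0$, so inclusion/exclusion is immaterial and inclusion
matches the "sum over all aligned residues" reading. Columns gapped in
either structure are flagged as gaps and excluded from n. The overall
statistic is reported as $\sqrt{\mathrm{mean}_i\,\mathrm{dRMSD}_i^2}$: the
quantity is called an RMSD and is plotted on the per-site axis, so the
root is taken by default, but because the defining phrase ("mean of the
squared contributions") can also be read literally, `sqrt_overall = FALSE`
emits the mean of squares and both values are carried on the profile
object.

Design properties, each tested: exact symmetry in the two arguments;
invariance under rigid motion of either structure (distance matrices do
not see rotations or translations), checked to < 1e-9 over 50 seeded
random transforms; zero overall iff the two restricted distance matrices
agree; and equality with a naive double-loop evaluation of the definition
to 1e-12 on random 5–15-residue fixtures.

Averaging over a pair of query structures against a common target is done
column-wise on the two profiles (gap in either ⇒ gap in the average), and
the overall value carried is the mean of the two overall values — i.e.
pairwise-then-average, never a pooled recomputation.

**Superposition.** For visual overlays the package uses classical
least-squares rigid-body fitting (Kabsch): SVD of the cross-covariance of
the centred aligned coordinates, with the sign of the smallest singular
direction flipped if needed so the rotation is proper (determinant +1;
reflections are never returned). This is a deliberate simplification — the
probabilistic joint sequence–structure superposition used in some
published figures is out of scope — and the dRMSD statistic is independent
of it by construction. Degenerate inputs (fewer than 3 pairs, collinear
points) are rejected.

**Fallback alignment.** When no curated summary alignment is available,
`structure_guided_alignment()` seeds a correspondence from a global
sequence alignment, superposes, re-pairs residues as mutual nearest Cα
neighbours within 5 Å filtered to a monotonic chain (longest increasing
subsequence), and iterates three times. 5 Å is a conventional
residue-equivalence cutoff for Cα pairing; three iterations suffice for
convergence on compact folds. Any comparison against published numbers
must state which alignment was used, because aligned-length and overall
values depend on it; the fallback is star-shaped against the first trace
and does not represent residues absent from the reference.

## Distance phylogeny

p-distances use pairwise deletion: each pair is compared over the columns
where both rows carry one of the 20 standard residues (`X` counts as
missing). The Poisson correction $d=-\ln(1-p)$ assumes substitutions
arrive as a Poisson process with uniform replacement; $p \ge 1$ is
reported as a saturation error rather than an infinite distance.
Neighbor joining follows Saitou–Nei exactly: the Q-criterion, ties broken
by the lowest index pair, branch lengths from the standard formulas,
negative branches clamped to zero with the total clamped deficit recorded
as a tree attribute (silently re-distributing the deficit would corrupt
path distances). NJ is exact on additive matrices; the tests check path
distances to 1e-9 on random additive matrices up to 12 taxa and
cross-check the topology against an independent NJ implementation.

Bootstrap resamples alignment columns with replacement, rebuilds
p/Poisson/NJ per replicate, and attaches to each internal branch of the
full-data tree the percentage of valid replicates containing its
bipartition. Replicates in which some pair has no comparable columns or is
saturated are dropped and counted — the alternative (imputing a large
distance) would manufacture support from missing data. An alignment with
no variation is an error, not a tree. Majority-rule consensus keeps
bipartitions in more than half of the input trees (mutually compatible by
construction) with frequency percentages as labels.

## What the generators emulate — and what they do not

`simulate_family()` evolves sites independently on a known tree: per
branch of length b, a Poisson(b) number of substitutions per site, each
replacing the residue with one of the other 19 uniformly. This is exactly
the regime the Poisson correction inverts, which is the point: it closes
the loop for the tree stage, so topology-recovery failures indicate
implementation defects rather than model mismatch. It does *not* emulate
real globin evolution — no site-rate heterogeneity, no exchangeability
structure (WAG-like matrices), no indels — so passing recovery tests says
nothing about accuracy under model misspecification. The canonical study
condition is the fixed 8-taxon tree of `default_family_tree()` (branch
lengths 0.05–0.3 substitutions/site, the divergence regime of globin
subfamilies) with 2000 sites.

`make_helical_template()` builds ideal α-helices (rise 1.5 Å/residue,
100°/residue, Cα radius 2.3 Å, giving consecutive-Cα distances near
3.8 Å) on a circular antiparallel bundle; `perturb_structure()` adds
isotropic Gaussian noise per Cα, an optional rigid transform, and deletion
spans (emulating, e.g., a disordered helix D), returning the ground-truth
column mapping. Correlated backbone noise and real loop geometry are not
modelled; the structures exist to give the dRMSD and superposition code
exact, controllable truth. At the default σ = 0.5 Å the overall dRMSD of
a 152-residue bundle concentrates in [0.4, 1.0] Å, the band asserted over
50 seeds.

`make_multidomain()` concatenates independently mutated copies of a domain
joined by low-complexity G/S/P linkers and returns the planted intervals;
linkers are deliberately unlike globin sequence so they cannot attract the
probe.

All generators are seed-deterministic: identical configurations produce
byte-identical output, which the tests assert.

## Numerical and interface choices

- Residue ordinals in alignments and domain intervals are 1-based
  (closed intervals), the R convention, throughout.
- PDB parsing (delegated to an established reader) uses the first MODEL
  only; alternate locations are resolved by highest occupancy with ties to
  the first encountered; HETATM records are excluded except
  selenomethionine (mapped to M); other non-standard residues become `X`,
  which is treated as a mismatch/missing everywhere. Which chain of a
  multi-chain entry to use is genuinely underdetermined for published
  comparisons; the default is the first chain containing a Cα, overridable
  by argument.
- Newick support values are written as internal node labels (integer
  percent); branch lengths round-trip to at least 6 significant digits.
- TSV outputs have a single header row with floats at 4 decimals.
- Workflow runs write a JSON manifest (package version, parameters, seed,
  MD5 digests of every output); all randomness in a run flows from the
  single seed, and deterministic outputs are byte-identical across reruns.
- The command-line surface is a thin wrapper
  (`inst/scripts/globinkit-cli.R`) over `run_sequence_workflow()` /
  `run_structure_workflow()`; the R functions are the primary interface.

Problem sizes in the test and acceptance runs — 100 simulated families of
2000 sites for topology recovery, 50 seeds for the rigid-motion and noise
bands, 25 random fixtures for the dRMSD oracle, bootstrap at 100–200
replicates — were chosen as the package's own balance between statistical
sharpness of the asserted bands and a suite that runs in well under a
minute per file.

## Limitations

- Likelihood and Bayesian tree inference, alignment construction, profile
  Z-score computation, and probabilistic structural alignment are out of
  scope; their outputs are consumed as inputs where relevant.
- The fold check is alignment-conditional: it validates a candidate *given*
  an alignment and inherits that alignment's biases (see above).
- The structure-guided fallback alignment is a pragmatic star alignment,
  not a joint multiple structural alignment; published aligned-length
  figures depend on the alignment used and can only be compared within
  stated tolerances.
- Comparisons against published values for real proteins require the
  corresponding external files (see `inst/extdata/external/README.md`);
  the package does not redistribute or fetch them.
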