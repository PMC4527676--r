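# Externally retrieved inputs (not redistributed)

The published-data integration check in `tests/testthat/test-acceptance.R`
compares package output against values reported for real data. The inputs
are not redistributable with the package and must be placed here by hand:

- `XP_001199205.2.fasta` — the 2146-residue sea urchin 14-domain globin
  protein sequence (GenBank accession XP_001199205.2), FASTA format.
- `similarity_matrix_52.tsv` — the published 52-sequence percent-identity
  matrix as TSV: first column and header row are sequence ids, cells are
  percent identities (diagonal 100).
- `1hlb.pdb`, `1hlm.pdb`, `1oj6.pdb`, `1urv.pdb` — PDB-format coordinate
  files for the two sea cucumber coelomic hemoglobins, human neuroglobin
  and human cytoglobin (https://files.rcsb.org/download/<ID>.pdb).

Without these files the integration check fails with a message naming what
is missing; all other checks are self-contained.
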