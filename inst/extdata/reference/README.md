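# External reference data (user-supplied)

The files below are *not* distributed with the package: they are
third-party database entries. The structure-comparison and
printed-mass checks in the test suite run against them when present;
without them those checks report failure rather than silently passing.

Place here:

- `AB277764_casq1_mature.fasta` — mature bovine Casq1 protein sequence
  (translate GenBank AB277764.1 and remove the signal peptide so that
  numbering starts at the mature N-terminus; the conserved
  glycosylation sequon is then Asn316-Val-Thr).
- `5KN0.pdb`, `5KN1.pdb`, `5KN2.pdb`, `5KN3.pdb` — bovine Casq1
  crystal structures from the PDB (low-Ca native, high-Ca recombinant,
  high-Ca native, low-Ca recombinant respectively), PDB format with
  REMARK 290.
- `casq_orthologs.fasta` — mature calsequestrin ortholog sequences
  with ids `btCasq1` and `rnCasq1` (bovine and rat skeletal isoforms).
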