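---
title: "Methods: calsequestrin PTM assignment and structure comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calsequestrin PTM assignment and structure comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casqtools)
```

## The scientific problem

Calsequestrin (Casq), the main Ca²⁺-buffer protein of the sarcoplasmic
reticulum, is post-translationally modified in transit to the
junctional SR: an N-linked high-mannose glycan (GlcNAc₂Manₙ) is
attached at the conserved sequon Asn316-Val-Thr, and the acidic
C-terminal tail of the cardiac isoform (Casq2) carries zero to two
phosphoryl groups. Both modifications modulate Ca²⁺-dependent
polymerization. `casqtools` implements the computational side of
characterizing these modifications: in-silico CNBr digestion with
glyco/phospho mass-ladder assignment of MALDI-TOF peak lists, and
crystal-structure comparison of glycosylated (native) versus
non-glycosylated (recombinant) Casq1.

## The assignment model

CNBr cleaves C-terminal to methionine and converts the cleaved Met to
homoserine lactone (the default chemistry here; ring-opened homoserine
and intact termini are selectable). For a peptide of neutral mass
$M$ carrying $a$ HexNAc, $h$ hexose and $p$ phosphoryl groups, the
expected singly charged ion is

$$ m/z = M + a\,\Delta_{\mathrm{HexNAc}} + h\,\Delta_{\mathrm{Hex}}
   + p\,\Delta_{\mathrm{HPO_3}} \pm m_{\mathrm{proton}} $$

with $+$ for positive and $-$ for negative polarity. On the average
mass scale $\Delta_{\mathrm{Hex}} = 162.14$ and
$\Delta_{\mathrm{HPO_3}} = 79.98$ — the +162 and +80 m/z spacings that
identify glycoform ladders and phosphopeptides on a spectrum. All mass
constants derive at load time from a single embedded atomic-mass table
(monoisotopic principal-isotope values; conventional standard atomic
weights for the average scale), so every downstream number is
reproducible from six elemental constants per scale.

`assign_compositions()` enumerates a finite composition grid, computes
each expected ion m/z, matches the nearest observed peak within a
tolerance, and accepts the match when the peak's signal-to-noise ratio
*strictly* exceeds a threshold (default 1.0). Each observed peak is
used at most once: candidate (composition, peak) pairs are consumed
greedily by smallest $|$error$|$, ties broken toward fewer total
modifications, then lower expected m/z. This greedy order makes the
accepted set monotone in the tolerance (shrinking the window can never
add assignments), a property the tests exercise. Compositions whose
expected masses coincide within 1 µDa are flagged ambiguous rather
than silently merged. Relative glycoform abundances are peak-height
fractions over the accepted assignments, as in the underlying
experimental convention.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `tolerance` | 1.0 | Da | printed peptide masses scatter by about ±1 Da at m/z 2500–5000 |
| `snr_threshold` | 1.0 | ratio | acceptance rule is S/N strictly greater than 1 |
| `comp_space` | HexNAc ∈ {0, 2}, Hex 0–9, phosphoryl 0–3 | counts | high-mannose glycans carry a GlcNAc₂ core; up to nine mannoses and (in canine Casq2) a possible third phosphosite are reported; HexNAc = 1 is searchable for truncated or ambiguously printed forms |
| `max_missed` | 1 | cleavages | CNBr digests are routinely incomplete; some reported peaks are only explicable as missed-cleavage fragments |
| `cterm_chem` | homoserine lactone | — | dominant CNBr product |
| charge | 1 | — | MALDI analyte peaks are interpreted singly charged |
| `estimate_snr` window | 200 | Da | local median of neighbouring peak intensities where no explicit noise channel exists; floored at 10⁻⁹ |

Scale/polarity pairing: reflector-mode spectra are read on the
monoisotopic scale and linear-mode on the average scale; negative mode
gives [M−H]⁻, positive [M+H]⁺. The experimental record does not state
which scale its printed masses use, so the accession-backed checks
calibrate the pairing (and homoserine chemistry) by minimizing the
error against the printed non-glycosylated peptide mass before testing
the glycoform — the pairing is selected on one quantity and held fixed
for the other.

## Structure comparison

`kabsch_superpose()` is an in-package implementation of least-squares
rigid superposition: center both coordinate sets, form the 3×3
covariance, take its SVD and apply the determinant correction so the
optimum is a proper rotation. The r.m.s.d. is
$\sqrt{\sum_i \lVert a_i - R b_i - t \rVert^2 / n}$. Tests compare it
against an independent closed-form quaternion (Horn) oracle on random
instances, and against the expectation
$\mathrm{rmsd} \approx \sigma\sqrt{3}$ for isotropic Gaussian
perturbation of one copy.

Comparisons mirror the published protocol: Cα atoms of residues Pro7
through Pro334 (domains I–III, excluding the α12 helix and the
flexible 350–354 loop), residues paired by author numbering and
intersected across the two chains, so residues unmodelled in either
structure drop out. Alternate locations are resolved to the
highest-occupancy conformer (ties toward altloc A). B-factor profiles
average backbone (N, CA, C, O) atoms per residue, average across the
chains of the asymmetric unit, and normalize by the grand mean — the
profile therefore has mean exactly 1 and is invariant to uniform
rescaling; "backbone" is taken as the common four-atom convention
since the source does not specify the set. Symmetry expansion consumes
REMARK 290 operators (already in orthogonal-Angstrom space) directly
from the file rather than an embedded space-group library, keeping
assemblies bit-traceable to the deposited entry. Ion counting is a raw
count of HETATM atoms of the element (occupancy weighting optional;
published Ca²⁺ counts read as integers).

## Sequence comparison

Percent identity/similarity matrices use global end-to-end alignment
with BLOSUM62 and affine gaps (open 10, extend 0.5), similarity
counting Clustal "strong"-group substitutions — the asterisk/colon
convention of alignment printouts. The percent denominator is the main
reproduction risk for published tables whose method is unstated: the
default is the length of the shorter sequence, with alignment length
and mean length selectable. The alignment engine is standard dynamic
programming (via Biostrings); the tests check its scores against an
independent memoized recursion on short strings, so the scoring
convention used here is pinned down rather than assumed.

## What the synthetic generators emulate — and what they do not

`simulate_sequence()` draws Met cleavage points independently per
position (probability 1/`met_spacing`), plants exactly one N-X-S/T
sequon 40 residues from the C-terminus (mimicking Asn316 in a
~370-residue mature chain), and builds an acidic tail with an exact
number of serines in the final 30 residues. `simulate_peaklist()`
places one peak per ground-truth composition with Gaussian mass error,
lognormal intensity jitter (sdlog 0.3, fixed) on a baseline of 1, and
uniformly scattered sub-threshold spurious peaks.
`simulate_coord_pair()` applies a quaternion-uniform random rotation,
a random translation and isotropic Gaussian perturbation. All
generators are bit-reproducible from their seed and restore the
caller's RNG state.

The spectra have no isotope envelopes, peak shapes, detector
saturation or multiply charged species, and the sequences have uniform
residue usage; passing the recovery benchmarks therefore demonstrates
correctness of the matching logic under calibrated noise, not
instrument-level realism. Glycan compositions are treated as
compositions only — branching isomers are out of scope, as in the
underlying experiment.

## Numerical choices and degenerate inputs

- Duplicate m/z within 10⁻⁶ and negative intensities are rejected at
  parse time; single-peak lists without a noise channel cannot be
  S/N-estimated and are rejected.
- Superposition requires ≥ 3 non-collinear points (rank check on the
  centered sets); size mismatches are rejected rather than truncated.
- Ladder detection links each peak to its nearest successor within the
  tolerance and reports maximal chains of length ≥ 2, based at the
  lowest-m/z member.
- Profile ties (equal peak heights) resolve toward fewer total
  modifications, keeping the major form deterministic.

## Problem sizes used by the test suite

The property surface runs at: 200 random superposition instances
against the quaternion oracle (tolerance 10⁻⁶ Å), 10,000-atom noise
calibration (±5%), 1,000 random sequences against the brute-force
splitter, 500 simulated spectra (mass error σ = 0.3 Da, 20% spurious
peaks, tolerance 1.0 Da) requiring ≥ 95% composition recovery, and 100
random short-string alignment pairs against the memoized recursion.
These sizes give stable pass/fail behaviour at fixed seeds while
keeping the default suite fast.

## Known limitations

- Reproducing the published peptide masses, r.m.s.d. table and
  identity matrix requires the external database entries (GenBank
  translation, PDB depositions, ortholog sequences) described in
  `inst/extdata/reference/README.md`; they are third-party data and
  not distributed. The corresponding checks fail visibly, rather than
  pass vacuously, when the files are absent.
- One reported inconsistency is deliberately left unresolved: a rat
  Casq2 "non-glycosylated" peak printed heavier than its
  GlcNAc₂Man₃ glycoform cannot belong to the same peptide series; the
  missed-cleavage search space (default `max_missed = 1`) is the
  mechanism by which such peaks can be explained as alternative
  fragments, but the package does not adjudicate.
- The aligner/denominator behind published identity tables is unknown;
  matrix values here are method-sensitive at the ±1 point level.
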