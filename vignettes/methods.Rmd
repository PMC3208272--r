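---
title: "Methods: homology-based miRNA precursor discovery and stem-loop stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based miRNA precursor discovery and stem-loop stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseeker)
```

## The problem

Conserved plant microRNAs can be identified in a transcriptome without a
reference genome by exploiting two facts: mature miRNAs (20–24 nt) are highly
conserved across angiosperms, and genuine precursors fold back into a stable
stem-loop carrying the mature sequence on one arm. `mirseeker` implements
this discovery pipeline for 454-style flower EST libraries from sexual and
apomictic *Boechera* genotypes, together with the downstream analyses built
on it: thermodynamic scoring of candidate hairpins, the effect of
species-specific nucleotide substitutions (NSs) on hairpin stability, and
expression comparisons (tag counts across ovule stages, microarray detection
calls, comparative ΔΔCt qPCR).

The real 454 libraries and the full multi-species reference snapshot are
external data; a seeded synthetic generator emulates them with known ground
truth, so every stage is testable end-to-end.

## Discovery pipeline

1. **Reference deduplication** (`dedup_mirnas`): mature miRNAs shared
   verbatim between species are collapsed to one record per distinct
   sequence. The kept record is the first after a `(species, id)` sort, so
   results do not depend on input order.
2. **Contaminant exclusion** (`filter_contaminants`): reads sharing an exact
   substring of ≥ *k* nt (default 20, either strand) with a tRNA/rRNA record
   are removed. The underlying exclusion rule ("exact matches") does not fix
   a match length, so *k* is exposed rather than guessed.
3. **Homology scan** (`gapless_scan`, `scan_library`): every full-length,
   gap-free window of each mature query is compared against both strands of
   every read; windows with Hamming distance ≤ 3 qualify. An exhaustive
   scanner replaces the original heuristic (word-size-7 BLASTn) because the
   libraries are desk-scale and exhaustiveness guarantees that anything the
   seeded search could find is found. Only full-query-length alignments are
   kept: a sub-length alignment cannot satisfy the length criterion, and the
   20–24 nt alignment-length window then follows from the query lengths.
   Per (family, read) the best hit is retained — fewest mismatches, then
   longest, then leftmost, then plus strand — a tie-break this module fixes
   for determinism because the original procedure leaves it unstated.
4. **Redundancy collapse** (`collapse_redundant`): candidates with an
   identical read window merge, carrying the union of family labels (the
   classic miR156/miR157 case where both families match the same read).
5. **Hairpin evaluation** (`evaluate_candidate`): candidate windows are
   folded and the five acceptance criteria applied (below).

## Folding model

`fold_mfe` is an exact dynamic program over a nearest-neighbour energy
model: stacking energies for the six pair types (AU, UA, GC, CG, GU, UG),
tabulated hairpin/bulge/internal-loop penalties with Jacobson–Stockmayer
log extrapolation, interior loops capped at 30 nt, and an affine multiloop
cost. There are no dangle or terminal-AU terms. The parameter table
(version `mirseeker-nn-1.0`) is embedded and versioned; energies are carried
as integer tenths of kcal/mol so that the dynamic program and the
brute-force reference agree *exactly*, with no floating-point ambiguity.

Numerical choices:

- sequences shorter than 8 nt cannot close a 3-nt hairpin loop and return
  an unstructured result at ΔG = 0;
- `N` never pairs;
- traceback preference is deterministic (unpaired before paired), so equal
  configurations always reproduce byte-identical dot-brackets.

`fold_enumerate` is the independent reference: it enumerates *every* nested
structure of a short sequence by backtracking and scores each by loop
decomposition (`score_structure`), sharing only the parameter table with the
DP. The test suite checks exact ΔG equality on 1000+ random sequences up to
28 nt. Bit-equality with any particular published folding engine is
deliberately not promised; agreement with an external thermodynamic backend
(`RNAfold`, when present) is checked as a rank correlation instead, and the
`backend = "vienna"` option exists for exactly such cross-checks. When the
substitution experiment folds a natural/corrected pair, both members always
use the same backend.

## Hairpin metrics and acceptance criteria

For a precursor of length NN folding to MFE (ΔG ≤ 0, kcal/mol):

- **AMFE** = |MFE| / NN × 100 — the folding energy normalized per 100 nt,
  reported as a positive magnitude (tables conventionally print positive
  AMFE against negative ΔG);
- **MFEI** = AMFE / (G+C%) with G+C% = 100 − A+U% — the index separating
  miRNA precursors (typically > 0.85) from tRNA/rRNA/mRNA.

Both definitions were verified for internal consistency against seven
published table rows before anything else was built on them. MFEI is
**reported, not filtered on**: published conserved precursors reach down to
MFEI 0.400, well below the 0.85 rule of thumb, so filtering would discard
genuine candidates.

A candidate is accepted when all five criteria hold:

1. ≤ 3 mismatches between the read's mature and the reference mature
   (inherited from the alignment; gap-freedom is enforced by construction);
2. the mature lies wholly on one arm of a stem-loop (`parse_hairpin`);
3. MFE ≤ −10 kcal/mol;
4. A+U content within 40–70% — applied to the **mature** sequence by
   default, which is how the criterion is stated; the table column used by
   MFEI is a precursor quantity and is always reported separately
   (`au_criterion_on = "precursor"` switches the criterion base);
5. the mature overlaps neither the terminal loop nor a multiloop, and
   contains at most 6 unpaired bases (configurable). A strict zero would
   reject real matures with small bulges.

**Window policy.** The precursor extents used in the original tables are
unrecoverable without the underlying records, so the window policy is this
package's own: fold the full read first, then symmetric extensions of the
hit by ±100, ±60 and ±20 nt, and keep the passing window with the most
negative MFE. The policy is configurable (`window_extents`) and recorded in
the run manifest.

## Substitution-stability experiment

`detect_ns` records position-wise differences between an observed mature and
its conserved reference (gapless by pipeline construction; ≤ 3 records by
criterion 1). `correct_precursor` rewrites exactly those positions inside
the precursor's mature span — in either direction, so the experiment runs
both ways: correcting observed matures to the reference nucleotides, and
giving reference precursors the observed nucleotides. A pair is called
stabilizing when ΔG(natural) − ΔG(corrected) < −0.05 kcal/mol; the 0.05
tolerance is half the one-decimal precision at which the published energies
are printed.

The pooled test is a one-sided Wilcoxon signed-rank (natural-more-stable).
The original analysis does not name its test; the signed-rank is chosen for
robustness at n = 18 paired energies, with a paired t-test behind
`method = "t"` for sensitivity. Because `stats::wilcox.test` cannot compute
exact p-values under ties — and printed one-decimal energies tie often — the
exact null is computed in-package by a generating-function convolution over
doubled mid-ranks (exact for n ≤ 25, tie-corrected normal approximation with
continuity correction above). It is verified against full 2ⁿ enumeration at
small n and against `wilcox.test` in tie-free cases. Whether the published
"p ≤ 0.05" refers to one pooled test or per-table tests is ambiguous, so the
pooled and per-mode tests are all computed and reported.

## Expression analyses

- **Targets** (`predict_targets`): gap-free antiparallel complementarity
  with a weighted mismatch budget of 3; G:U wobbles cost 0.5 (common plant
  target-scoring practice; the plain three-mismatch rule is `gu_weight = 1`,
  whose hit set is provably a subset of the 0.5-weight set).
- **Microarray calls** (`microarray_detect`): detected iff mean signal
  > 3 × background SD, spot CV < 0.5 and channel p < 0.01. The channel
  p-value's underlying test is vendor-side; the rule consumes a supplied
  p-value and documents that assumption.
- **Tag counts** (`diff_expression`): per stage, counts are pooled per
  reproductive mode and the 2×2 table (tag vs library remainder) is tested
  with Fisher's exact test, two-sided — exact at small counts, standard for
  tag data; the original procedure is unstated.
- **qPCR** (`ddct`): comparative ΔΔCt against a housekeeping reference and a
  calibrator sample; fold = 2^−ΔΔCt, invariant to shifting a sample's target
  and reference Ct together.

## Synthetic data: what it emulates, and what it does not

`gen_est_library` emits two libraries whose read lengths span 51–478 nt with
~80% near 200 nt (matching the stated library profile), planted hairpins of
66–233 nt built by `make_hairpin_precursor` (lower stem + mature arm +
loop + star arm, exact spans recorded), truncated one-arm fragments (short
reads that produce homology hits but cannot fold — emulating the observed
truncated precursors), verbatim contaminant copies, and homopolymer
insertion/deletion noise restricted to runs ≥ 2 nt, the characteristic
454 error mode. Background composition is uniform ACGU with an A+U bias
parameter, default 0.55, consistent with the 42–63% A+U range of plant
precursors; the real libraries' composition is unstated, so the bias is a
free knob, not a claim. All randomness flows from a single integer seed and
identical configurations reproduce byte-identical outputs.

What passing tests on this generator do **not** show: realistic 454
flowgram error structure, transcriptome-level expression realism, secondary
structure of real flanking sequence, or paralog families with partial
homology. Recovery rates on synthetic data bound the pipeline's
correctness, not its field sensitivity.

Problem sizes used by the test-suite and workflow runs — 500-read libraries
with 25 planted precursors, 1000-sequence folding-oracle sweeps at ≤ 28 nt,
1000-tag null calibrations at depth 10⁵, 20-sample qPCR recovery — are the
package's chosen defaults for a thorough desk-scale validation.

## Known limitations

- The folding model omits dangles, terminal-AU penalties, coaxial stacking
  and special hairpin loops; its absolute ΔG values differ from full Turner
  models (ranks track well, which is what the acceptance criteria use).
- Interior loops above 30 nt are disallowed rather than extrapolated.
- Contaminant screening is exact-substring, not similarity-based.
- The family-level merge map (miR156/157, miR170/171) for set comparisons
  is explicit configuration, not inference.
- The single intraspecific (sexual↔apomictic) miR394 comparison is supported
  by `correction_experiment` but its published magnitude is not reproducible
  without the underlying sequence.
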