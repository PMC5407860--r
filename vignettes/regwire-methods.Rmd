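---
title: "Methods: promoter interactome dynamics with regwire"
author: "regwire authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter interactome dynamics with regwire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regwire)
library(data.table)
```

## The analysis

Promoter Capture Hi-C (PCHi-C) enriches a Hi-C library for ligation
products involving baited promoter-containing restriction fragments, so
that individual promoter–enhancer contacts can be scored at
single-fragment resolution. `regwire` implements the downstream analysis
of such an experiment across two cell states (by default labelled ESC, a
pluripotent state, and NEC, a neuroectoderm-committed state):

1. **Interaction calling.** CHiCAGO-style scores (−log-transformed
   weighted p-values) are consumed per bait–otherEnd fragment pair. A
   pair is significant in a cell type when its merged score reaches 12,
   or falls in the rescue band [11, 12) while scoring ≥ 12 in the other
   cell type. The rescue rule only ever adds calls, so the threshold-12
   set is always a subset of the rescued set.
2. **Chromatin states.** A 16-state segmentation is curated into six
   broad states (states 1–6 active, 7–9 poised, 10 Polycomb-associated,
   11–12 mixed, 13 intermediate, 14–16 background), and each restriction
   fragment receives one broad state by presence-based priority rules:
   functional states beat background; active, poised and Polycomb beat
   intermediate; poised beats Polycomb; active co-occurring with a
   repressed state yields mixed.
3. **PIR enrichment.** Promoter-interacting regions (PIRs) are compared
   with distance-matched random fragments: each control fragment matches
   a randomly chosen bait at a distance in the same log10 bin (20 bins
   over the observed range) as a real PIR. Enrichment is summarised by
   the one-sided permutation p-value `(1 + #{perm ≥ obs}) / (n_perm + 1)`
   and a z-score.
4. **Topology.** Contact matrices are balanced by iterative correction.
   Directionality indices (DI) contrast the 1 Mb of contacts upstream
   versus downstream of a 25 kb window advanced in 5 kb steps, using the
   Dixon-form statistic `sign(B − A)·((A − E)²/E + (B − E)²/E)` with
   `E = (A + B)/2`. The DI track is smoothed by an 11-point running mean
   and z-standardised per chromosome. TADs run from a local DI maximum to
   the following minimum when their standard-score difference (TAD ΔZ)
   exceeds 2.0, with ends extended over bins with no directionality bias;
   boundary strength (TADB ΔZ) is the extremum difference across each
   inter-TAD boundary. A/B compartments come from the leading eigenvector
   of the distance- and coverage-corrected contact correlation matrix at
   250 kb, sign-aligned to an active-mark track, with |value| > 10
   defining A/B and the band in between "neither".
5. **Cis-regulatory units (CRUs).** Each protein-coding promoter with at
   least one significant PIR defines a CRU: the promoter plus all of its
   PIRs. CRUs are characterised by the fractions of assignable PIRs in
   the active, poised and Polycomb states (mixed and intermediate PIRs do
   not contribute; CRUs with only such PIRs are dropped), their genomic
   span, and their containment within TADs, and are clustered by
   Euclidean average-linkage on the state-fraction vectors (cut at eight
   clusters by default). Classes are single-state active, single-state
   repressed, dual, or background.
6. **Dynamics.** Retained interactions score ≥ 12 in both replicates of
   both cell types. Rewired candidates score ≥ 12 in both replicates of
   one cell type and < 12 in both replicates of the other; candidates are
   then placed into five equal-size merged-score bins per cell type and
   called rewired when they occupy the top bin of the high cell type and
   the bottom bin of the other. Recolouring is a change of a PIR's broad
   state between cell types. Fisher tests relate rewiring to recolouring
   and CRU class transitions to differential expression (padj < 0.05 and
   |log2FC| > 1.5); one-sided Wilcoxon rank-sum tests ask whether genes
   gaining an active PIR (by recolouring of retained interactions, or by
   rewiring) are up-regulated relative to genes losing one.

## The synthetic study

All tests run against `simulate_pchic_study()`, which plants a small
two-cell-type genome with a full ground-truth manifest. The default
configuration, which defines the study conditions everywhere in the
package, is:

* two chromosomes of 6 Mb, tiled by exponential(4 kb) restriction
  fragments clipped to [500 bp, 50 kb]; 150 baits, 90% protein-coding;
* eight TADs per chromosome (within-TAD contact enrichment 4×) and an
  alternating 750 kb A/B compartment checkerboard (contact modulation
  ±40%) whose block-transition bins are planted as belonging to neither
  compartment; contacts decay as `(1 + d)^-1` from a baseline of 300
  expected counts at distance zero, Poisson-sampled;
* 150 shared, 75 ESC-only and 75 NEC-only planted interactions — a
  desk-scale shadow of the full-scale retained/rewired sets — plus 60
  sub-threshold and 1000 background pairs. Class score means are 20
  (shared), 30/1.5 (cell-type-specific high/low), 9 and 3, with Gaussian
  replicate noise of sd 0.5 floored at zero. Planted PIRs sit inside
  their bait's TAD with probability 0.85, about four per interacting
  bait;
* 25% of retained PIRs recolour between cell types, preferring switches
  into and out of the active state; cell-type-specific PIRs carry
  active-biased states in their own cell type, and the single
  `recolour_fraction` knob scales all state changes, so setting it to
  zero freezes every PIR state;
* genes whose CRUs gain active PIRs in the committed state draw log2
  fold changes around +3 (losses around −3, others around 0, noise sd
  0.3); planted DE genes carry padj 10⁻⁶, others uniform(0.05, 1), and
  the DE flag applies the padj < 0.05, |log2FC| > 1.5 rule.

The generator emulates processed inputs only: scored interaction tables,
segmentations, binned matrices, expression tables and feature intervals.
It does not model capture bias, read-level noise, replicate-specific
background structure, trans contacts, or the weighted multiple-testing
behaviour of a real interaction caller — so green tests demonstrate that
the pipeline's logic recovers planted structure, not that any particular
biological dataset would behave as cleanly.

## Numerical and design choices

* **Merged scores.** When an input table lacks merged-score columns the
  replicate mean is used. The significance and replicate thresholds are
  applied as ≥ 12 (and the rescue band as 11 ≤ s < 12).
* **Distances** are fragment-midpoint separations: symmetric and
  insensitive to fragment size.
* **Quintile binning of rewired candidates** defaults to bin edges from
  the full per-cell-type merged-score distribution (`bin_mode =
  "global"`). Binning the candidates alone cannot mark the whole of a
  well-separated cell-specific class as rewired — a top bin of candidates
  holds 20% of them by construction — whereas the full-distribution
  reading makes the classifier consistent: a noiseless study is recovered
  exactly. The candidates-only variant remains available as `bin_mode =
  "candidates"`. Ties break deterministically by (score, bait id,
  other-end id).
* **TAD extrema.** Candidate maxima/minima must exceed the
  no-directionality-bias epsilon (|z| > 0.25 by default): tiny noise
  wiggles adjacent to a true boundary extremum would otherwise pair with
  it and truncate TADs. Plateaus take their midpoint index. Because the
  ±25 kb smoothing shifts extrema about half a window outward, boundary
  positions are read as the maximum's window start and the minimum's
  window end. Standardisation is per chromosome, keeping ΔZ comparable
  across chromosomes of different coverage.
* **Compartment values** are scaled to a maximum magnitude of 42 — the
  conventional range of printed principal-component values for this
  analysis — so that the ±10 A/B cutoff keeps its meaning (`scale_mode =
  "raw"` disables this). The expected matrix is the per-diagonal mean;
  zero-variance bins are masked; a per-chromosome override selects a
  later principal component where the first tracks arm-level structure.
  Planted "neither" bins are A/B block transitions: an isolated
  neutral bin in the middle of a compartment block inherits its
  neighbourhood's sign through the correlation structure, which is a
  property of the O/E-correlation construction itself, not a calling
  error.
* **Permutation nulls.** Control sets are duplicate-free and exclude
  true PIRs; empty distance bins widen to the adjacent bin with a
  warning. The CRU containment null relocates each CRU's bait to a
  random promoter fragment with all PIR offsets preserved (PIRs pushed
  past a chromosome end are dropped for that permutation); baits
  straddling a domain boundary, or outside every domain, are excluded.
  The null-calibration test sizes its fixture (3200 PIRs over an
  80000-fragment universe) so that the integer overlap count spreads
  widely; the permutation p-value is discrete (51 atoms) and
  tie-conservative by construction, and with narrower counts that
  discreteness — not any miscalibration — would dominate a
  goodness-of-fit comparison against the continuous uniform.
* **Degenerate inputs.** Zero-variance permutation distributions report
  `z = NA`; all-zero matrix rows are masked by the balancing; a constant
  DI track standardises to zero with a warning; fragments with no
  segmentation coverage become background with a warning; Haldane's
  +0.5 correction is applied to zero cells of 2×2 tables.

## Problem sizes used by the tests

The test suite and the acceptance script run the default study (≈3000
fragments, 1360 scored pairs, 240-bin contact matrices), 200-seed null
replicates on a reduced single-chromosome study, and 500-run permutation
calibrations, totalling a few minutes of compute. These sizes are the
package's chosen desk-scale study conditions; the pipeline itself is
agnostic to scale.

## Known limitations

* The interaction caller's internal background model is out of scope:
  scores are consumed as given, and the rescue rule is applied to merged
  scores only (replicate support is not re-checked at rescue time).
* Tissue-activity z-scores for enhancer annotations use the same
  distance-matched permutation scheme restricted to the annotated
  elements; the construction is recorded in the output rather than
  inherited from any external definition.
* A/B compartment overlap with rewiring events is not part of the
  analysis surface.
* With very small candidate sets (< 5) the rewired classifier returns an
  empty set rather than degenerate quantile bins.

## A worked run

```{r example, eval = FALSE}
study <- simulate_pchic_study(synthetic_config(seed = 1))
calls <- call_significant(load_scores(study$scores, study$fragment_map))
states <- lapply(c("ESC", "NEC"), function(cc) {
  fragment_states(study$fragment_map, study$segmentations[[cc]], cc)
})
names(states) <- c("ESC", "NEC")
crus <- build_crus(calls, study$fragment_map, states$ESC, "ESC")
dyn <- classify_recolouring(
  filter_rewired_retained(calls, states_a = states$ESC,
                          states_b = states$NEC),
  states$ESC, states$NEC)
rewiring_recolouring_association(dyn)
```

The same computation, staged over an on-disk study, is available as
`run_pipeline()`; `scripts/acceptance.R` in the source repository runs it
end to end and writes the headline quantities as JSON.
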