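---
title: "Methods: rule-based ERK/MAPK subtyping of IDH-wild-type glioblastoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based ERK/MAPK subtyping of IDH-wild-type glioblastoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioclass)
```

## The classification model

IDH-wild-type glioblastomas carry largely non-overlapping driver
alterations in the receptor tyrosine kinase (RTK) / RAS--RAF segment of the
ERK/MAPK signalling pathway. `glioclass` turns that observation into a
deterministic, rule-based partition of a cohort into mutually exclusive
molecular subgroups:

* **DMG** — histone H3 K27M-positive diffuse midline glioma, triaged out of
  the numbered scheme by IHC before any genomic rule runs;
* **IDH** — IDH1 R132H IHC positivity or a pathogenic IDH1/IDH2 variant;
* **G1/EGFR** — a lone EGFR driver, split into EGFR-amplified (G1↑) and
  EGFR-mutant-only (G1m) cases;
* **G2/FGFR3**, **G5/PDGFRA** — a lone FGFR3 or PDGFRA driver;
* **G6/Multi-RTK** — two or more concurrent RTK drivers, PDGFRA
  amplification without overexpression, or a lone driver in a
  non-canonical RTK (MET, NTRK1, FGFR2, ALK, EPH receptors, ...);
* **G3/NF1** — NF1 inactivation (usually biallelic) with no RTK driver;
* **G4/RAF** — activating BRAF or RAF1 mutation with no RTK driver;
* **G7/Other** — no ERK/MAPK driver found.

A gene counts as an RTK *driver* when it is amplified (copy number ≥ 7)
and either overexpressed (≥ 5-fold over low-grade glioma controls) or of
unknown expression; or carries a curated activating mutation; or a
pathogenic in-frame fusion; or — for MET only, by default — is very highly
overexpressed (≥ 10-fold) without amplification but with a low-level
chromosome-7 copy gain. Rules are evaluated in a fixed order (IHC triage,
driver set, NF1, RAF, Other), so every case receives exactly one label and
the partition property is testable.

Three deliberate refinements to the plain rule list, each motivated by
cases the plain rules would misroute:

* *Amplicon collapsing.* PDGFRA, KIT and KDR are contiguous on 4q12 and
  co-amplify; co-amplified neighbours whose only evidence is amplification
  are collapsed into a single locus driver, so a PDGFRA/KIT/KDR-amplified
  tumor is a G5 case, not Multi-RTK.
* *Silent PDGFRA amplification.* The Multi-RTK override for
  amplified-but-not-overexpressed PDGFRA applies only when PDGFRA has no
  other driver evidence. The amplified-and-overexpressed fold range starts
  at 4.9 — marginally below the 5-fold cut — and such borderline cases
  carry concurrent activating missense mutations; they belong in G5.
* *Monoallelic NF1.* A single pathogenic NF1 hit without a detectable
  second hit still classifies as G3, flagged `monoallelic`; nearly all,
  but not all, NF1 tumors show two hits.

Tie-breaking between an RTK driver and simultaneous NF1/RAF evidence (a
configuration never observed in the emulated cohort) resolves in favour of
the RTK subgroup and sets a `conflict` flag, because the RTK subgroups are
defined first and by positive driver evidence.

## Alteration calls and their thresholds

| call | rule | default |
|---|---|---|
| amplification | copy number ≥ threshold | 7 |
| overexpression | fold-change ≥ threshold | 5 |
| high-fold driver arm | fold ≥ high_fold, no amplification | 10 (MET only) |
| TERT activation | promoter mutation, else overexpression | 5-fold |
| MGMT methylation | quantitative value ≥ threshold | 5 |
| biallelic loss | 2 pathogenic hits, or 1 + LOH, or homozygous loss | — |

Fold-changes divide each tumor's count by the arithmetic mean of the
low-grade glioma control samples, after removing genes that never reach
500 raw counts in any tumor, pseudogenes, and Y-chromosome genes. Genes
with a zero control mean cannot be expressed as a ratio; they carry an
`NA` sentinel and never enter thresholding. Library-size (CPM)
normalization before the ratio is available as a toggle but off by
default, since the counts the pipeline emulates are already normalized
upstream and the control-versus-tumor ratio cancels global scale.

One deliberate choice concerns the TERT composite: with a wild-type (or
uncovered) promoter and no expression data the telomerase-activation
status is *indeterminate*, not negative. This matters for frequency
reporting — the reference profile's TERT row uses assessed-case
denominators (e.g. 28 of 33 EGFR-amplified cases), and treating
unassessable cases as negative would make several of its cells
unreachable.

## The frequency matrix

`frequency_matrix()` reports, per subgroup, the percent of cases carrying
each single-gene alteration (pathogenic small variants; amplification for
CDK4/MDM2/MDM4/YEATS4; homozygous loss for CDKN2A) and each composite
pathway status (PI3K/mTOR, cell-cycle G1 phase, p53, DDR, mismatch
repair, SWI/SNF, chromatin remodelling, TERT, MGMT). Variants of unknown
significance never count. Per-cell denominators are the cases with that
feature assessed; empty subgroups yield missing cells, not zeros. The
whole-cohort column is recomputed from the data. Two totals of the
reference profile are not arithmetically consistent with their own
per-subgroup cells (PIK3CA and STAG2 columns imply 16.1% and 11.5%, not
the printed 18.4% and 12.6%); the package reports the data-consistent
values and the regression tests pin every per-subgroup cell plus the
consistent totals.

## Subgroup clustering

Each subgroup becomes a feature vector: its frequency-matrix column plus
its mean CDK6 fold-change and mean proliferation score (mean MKI67 fold by
default). Subgroups are then correlated (Pearson) and clustered
agglomeratively on the distance `1 - r`, with lexicographic leaf ordering
for deterministic ties, and exported to Newick if desired.

Two open choices were resolved by measurement on the reproduced matrix:

* **Scaling.** Correlating the raw vectors (percent-dominated) reproduces
  the expected structure — EGFR-amplified and NF1 as the tightest pair,
  a cluster of EGFR↑/NF1/RAF joined by FGFR3, a second cluster of
  Multi-RTK/Other, and PDGFRA, EGFR-mutant and IDH segregating. Z-scoring
  each feature first inflates near-constant rows (PPM1D, MDM4 are almost
  everywhere zero) and scrambles the top pair; it remains available as
  `correlation_matrix(..., scale = TRUE)` for sensitivity analysis but is
  off by default.
* **Linkage.** The linkage method behind the reference dendrogram is not
  stated. Complete linkage reproduces the full first cluster
  {EGFR↑, NF1, RAF, FGFR3}; under average linkage FGFR3 attaches to the
  Multi-RTK/Other side first. The tests assert the linkage-robust core and
  log this divergence rather than hiding it.

## Survival and demographics

Kaplan–Meier estimation and the log-rank (Mantel–Cox) test are delegated
to the `survival` package behind thin accessors implementing the
pipeline's conventions: the median is the first time the curve reaches
0.5 (undefined for all-censored input), landmark survival is step
interpolation carrying the last estimate forward, and deaths precede
censorings at tied times. Demographic summaries report age mean ± SEM
with outliers excluded by the Tukey 1.5×IQR fence (the outlier rule in
the source figures is not defined; Tukey fences are the conventional
choice), male-to-female and White-to-Black ratios with missing ethnicity
excluded from denominators, and pairwise Welch t-tests on age reported
raw — with a clearly-labelled Holm-adjusted column added as an extension.

## Histology

The 12 morphologic patterns map totally and deterministically onto five
clusters (EGFR-like, Small neuronal-like, Anaplastic, Spindle,
Epithelioid). Pattern assignments not fixed by the morphological
descriptions (the irregular small-dark-nuclei and pleomorphic patterns)
default to the Anaplastic cluster and are tagged `inferred` in the
configuration, so inferences are never presented as settled fact and can
be overridden per analysis. Histologic–molecular association uses
two-sided Fisher exact tests on per-(cluster, feature) 2×2 tables.

## The synthetic cohort

The generator is first-class, tested code; its defaults *are* the study
conditions the analysis assumes, and they are not adjusted per run:

* subgroup sizes 33/3/7/7/5/15/4/13 (plus 7 IDH-mutant, 3 DMG and 4
  IHC-only cases to reach the 101-patient cohort shape);
* per-subgroup alteration frequencies equal to the reference profile,
  sampled with mutual exclusivity of the G1-phase events (exactly two
  heterozygous germline RB1 point-variant exceptions cohort-wide, planted
  as VUS so they do not enter the pathogenic RB1 row), mutual exclusivity
  of the p53-pathway partner genes, and a configurable negative
  TP53/CDKN2A co-occurrence odds ratio (default 0.3, an inference from the
  observed inverse relationship, not applied in the NF1 and IDH columns);
* overexpression folds from range-truncated log-normals matched to the
  reported distributions — EGFR-amplified mean 26 (SEM 3.7, n = 33,
  converted to an SD via √n) truncated to [4.5, 72]; PDGFRA mean 16.8
  truncated to [4.9, 25.7]; MET-amplified above 40-fold;
* exponential survival with medians (months) 12 (EGFR↑), 6 (EGFRm),
  20 (FGFR3), 12 (PDGFRA), 7.5 (Multi-RTK), 6.7 (NF1), 3.5 (RAF),
  10 (Other) and 30 for IDH (the IDH median is not printed; 30 months is
  a conventional value for IDH-mutant glioblastoma), with 10% independent
  exponential censoring.

Event counts per cell are drawn by stochastic rounding of the expected
count (each case's marginal probability equals the configured frequency;
the across-seed mean is exact). This finite-population-style noise model
was chosen so that seed-averaged frequency-recovery audits remain sharp
for the 4–7-case subgroups, where fully independent per-case draws would
need hundreds of seeds to average out. Composite counts inherit the
members' noise with the overlap structure held at its reference value.

The **deterministic fixture** (`deterministic_fixture()`) is the
non-random counterpart used by all exact tests: per-subgroup event counts
equal `round(frequency × n)` for every cell, laid out case by case so that
all documented exclusivity constraints hold, histologic patterns align
with the planted mutations (every EGFR-like case carries the CDKN2A/2B
loss; the epithelioid cluster is 70% TP53- and 40% RB1-mutant), and two
assays have partial coverage (TERT assessed in 80 of 87 IDH-wild-type
cases, MGMT in 72) because several reference cells are only reachable
with reduced denominators. Survival times are exponential quantiles with
every tenth case censored, plus the two documented 7-year survivors in
the EGFR-amplified and FGFR3 subgroups.

What the generator does *not* emulate: read-level data, the vendor's
normalization, tumor mutation burden, co-occurrence structure beyond the
documented constraints, multifocal sampling beyond two flagged
secondary-focus events, and real inter-patient heterogeneity of effect
sizes. Passing recovery tests therefore demonstrates that the pipeline's
logic is faithful and stable under the assumed statistical structure —
not that it would classify any particular external cohort correctly.

## Numerical and degenerate-input choices

* Boundary values are inclusive everywhere (CN 7 amplifies, fold 5.0
  overexpresses, MGMT 5 is positive).
* Counts planted in the fixture round half away from zero.
* A case with no molecular data and negative IHC classifies as G7 with a
  warning and a `no_molecular_data` flag, and is excluded from every
  IDH-wild-type denominator (as are DMG cases).
* Zero-variance feature vectors abort clustering with the offending
  subgroup named; a zero-record survival group aborts the log-rank test.
* Problem sizes in the test-suite calibration studies — 2000 draws for
  the closed-form envelope, 500 per survival-median recovery, 100 seeds
  for label recovery, 200 seeds for log-rank power — were chosen as the
  smallest sizes at which the corresponding sampling envelopes are
  comfortably separated from the assertion bounds.

## Known limitations

* Pathogenicity and "activating" annotations are curated inputs, not
  re-derived from HGVS; variant-effect prediction is out of scope.
* The EGFRm subgroup has only three cases; every statement about it is
  fragile by construction, as in the source cohort.
* The two reference-profile totals that disagree with their own subgroup
  cells cannot be reproduced exactly by any cohort; the package sides
  with the arithmetic.
* Histologic patterns are expert labels; no image analysis is attempted.
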