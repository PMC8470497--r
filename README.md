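# glioclass

Rule-based, multi-platform molecular subtyping of IDH-wild-type
glioblastoma along the ERK/MAPK pathway.

## The problem

Adult IDH-wild-type glioblastoma is molecularly heterogeneous, but its
driver alterations in the receptor tyrosine kinase (RTK) / RAS–RAF segment
of the ERK/MAPK pathway are largely **mutually exclusive**. That makes a
deterministic, auditable partition possible: every tumor is assigned to
exactly one of seven subgroups,

| label | defining evidence |
|---|---|
| G1/EGFR (↑ or m) | lone EGFR driver — amplification (CN ≥ 7) with overexpression (≥ 5-fold), activating mutation, or fusion |
| G2/FGFR3 | lone FGFR3 fusion or activating mutation |
| G3/NF1 | NF1 inactivation (usually biallelic), no RTK driver |
| G4/RAF | activating BRAF/RAF1 mutation, no RTK driver |
| G5/PDGFRA | lone PDGFRA driver |
| G6/Multi-RTK | ≥ 2 concurrent RTK drivers, silent PDGFRA amplification, or a lone non-canonical RTK driver |
| G7/Other | no ERK/MAPK driver |

with histone H3 K27M-positive diffuse midline glioma (DMG) and IDH-mutant
tumors triaged out first by immunohistochemistry. The package is written
for computational neuro-oncologists and methodologists who want this
classification as reusable, tested code: per-gene alteration calling,
the subgroup classifier, composite pathway scoring, a subgroup × feature
frequency matrix, correlation-based hierarchical clustering of subgroups,
Kaplan–Meier survival stratification, histologic pattern mapping,
per-case pathology-style JSON reports — and a synthetic cohort generator
that emulates the 101-patient study conditions the analysis assumes, so
the whole pipeline is exercisable end to end without access to protected
patient data.

Alteration calls use the field's conventions: amplification at gene-level
copy number ≥ 7; overexpression at ≥ 5-fold over the mean of low-grade
glioma control samples (genes below 500 raw counts in every tumor,
pseudogenes and Y-chromosome genes excluded); TERT activation as promoter
mutation or, failing that, TERT overexpression; MGMT promoter methylation
positive at a quantitative value ≥ 5; biallelic inactivation as two
pathogenic hits, one hit plus LOH, or homozygous loss.

## Worked example

```r
library(glioclass)

co <- deterministic_fixture()            # the 101-case emulated cohort
sc <- classify_cohort(co, verbose = TRUE)
#> subgroup counts: DMG=3 IDH=8 G1_EGFR_amp=33 G1_EGFR_mut=3 G2_FGFR3=5
#>   G3_NF1=15 G4_RAF=4 G5_PDGFRA=7 G6_MultiRTK=7 G7_Other=16

s <- classification_summary(co, sc)
sprintf("RTK subgroups: %.1f%%  EGFR subgroup: %.1f%%  ERK/MAPK-altered: %.0f%%",
        s$rtk_pct, s$egfr_pct, s$mapk_pct)
#> "RTK subgroups: 63.2%  EGFR subgroup: 41.4%  ERK/MAPK-altered: 85%"
```

The 87 sequenced IDH-wild-type cases split 33/3/7/7/5/15/4/13 across
G1↑/G1m/G5/G6/G2/G3/G4/G7; the three IHC-only cases fall into G7 with a
`no_molecular_data` flag and are excluded from every denominator. The
frequency matrix gives per-subgroup alteration percentages (denominators
are the cases with each feature assessed):

```r
fm <- frequency_matrix(co, sc)
round(fm$matrix[c("TERT", "PTEN", "CDKN2A_loss", "CDK4_amp", "TP53"),
                c("EGFR_amp", "NF1", "Other", "Total")], 1)
#>             EGFR_amp  NF1 Other Total
#> TERT            96.4 73.3  81.8  85.0
#> PTEN            48.5 46.7  69.2  52.9
#> CDKN2A_loss     72.7 60.0  15.4  55.2
#> CDK4_amp         3.0  0.0  46.2  11.5
#> TP53            18.2 33.3  53.8  33.3
```

CDK4 amplification concentrates in the Other subgroup (46.2%, 6 of its 10
IDH-wild-type occurrences) while CDKN2A/2B loss dominates the
EGFR-amplified subgroup — the complementary G1-phase routes to cell-cycle
activation. A per-case report bundles everything a sign-out needs:

```r
case_report(co, "Pd03")
#> == Pd03 ==
#> Molecular subgroup: G5_PDGFRA
#> Drivers: PDGFRA:amplification
#> Histology: hgne (cluster Anaplastic)
#> Pathways altered: tert_path, pi3k_mtor, g1_phase, tp53_path, ddr_path
#> MGMT promoter methylation: negative
#> [config a91ec6b2, glioclass 0.1.0]
```

Downstream, `subgroup_feature_vectors()` + `correlation_matrix()` +
`cluster_subgroups()` reproduce the two-cluster structure of the
subgroups (EGFR↑/NF1/RAF/FGFR3 versus Multi-RTK/Other, with PDGFRA,
EGFR-mutant and IDH segregating), `km_fit()`/`logrank_test()` stratify
survival, and `generate_cohort(generator_config(seed = ...))` draws fresh
randomized cohorts with the same statistical structure. A thin CLI wraps
the same functions:

```sh
Rscript inst/cli/glioclass.R simulate --seed 7 --out cohort/
Rscript inst/cli/glioclass.R classify cohort/ --out calls.tsv
Rscript inst/cli/glioclass.R report cohort/ --case S-NF1-001
```

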