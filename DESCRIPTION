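Package: glioclass
Title: ERK/MAPK Pathway-Based Molecular Subtyping of IDH-Wild-Type Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based multi-platform classification of IDH-wild-type
    glioblastoma into seven mutually exclusive molecular subgroups (G1/EGFR,
    G2/FGFR3, G3/NF1, G4/RAF, G5/PDGFRA, G6/Multi-RTK, G7/Other) from
    gene-level variant, copy-number, fusion and expression tables. Includes
    deterministic per-gene alteration calling (amplification at copy number
    >= 7, overexpression at >= 5-fold over low-grade glioma controls, TERT
    activation, MGMT promoter methylation, biallelic inactivation), composite
    oncogenic pathway scoring, a subgroup-by-feature frequency matrix,
    correlation-based hierarchical clustering of subgroups, Kaplan-Meier
    survival stratification, histologic pattern-to-cluster mapping, a
    synthetic cohort generator emulating the study conditions, and per-case
    pathology-style reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
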