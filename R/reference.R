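#' @keywords internal
"_PACKAGE"

## Closed vocabularies for the clinical interchange tables -------------------

GBM_SEX <- c("M", "F")
GBM_ETHNICITY <- c("White", "Black", "Other")
GBM_LOCATION <- c("frontal", "temporal", "parietal", "other_lobe",
                  "midline", "corpus_callosum")
GBM_IHC_3 <- c("positive", "negative", "missing")
GBM_GFAP <- c("high", "low", "absent", "missing")
GBM_VARIANT_KINDS <- c("missense", "truncating", "frameshift", "splice_variant",
                       "promoter_mutation", "fusion", "amplification",
                       "homozygous_loss", "loh", "cn_gain")
GBM_PATHOGENICITY <- c("pathogenic", "likely_pathogenic", "vus", "unknown")

## The 12 histologic patterns (morphology vocabulary of the classification).
GBM_PATTERNS <- c("egfr", "egfr_fgfr", "fgfr_small", "small_dark_reg",
                  "small_dark_irreg", "pre_hgne", "hgne", "fibroblastic",
                  "gliosarcoma", "giant_cell", "epithelioid", "pleomorphic")

GBM_HISTO_CLUSTERS <- c("EGFR_like", "Small_neuronal", "Anaplastic",
                        "Spindle", "Epithelioid")

## Subgroup labels ------------------------------------------------------------

GBM_LABELS <- c("DMG", "IDH", "G1_EGFR_amp", "G1_EGFR_mut", "G2_FGFR3",
                "G3_NF1", "G4_RAF", "G5_PDGFRA", "G6_MultiRTK", "G7_Other")

## Column order used throughout for the IDH-wild-type subgroups (+ IDH-mutant)
GBM_SUBGROUP_COLS <- c("EGFR_amp", "EGFR_mut", "PDGFRA", "MultiRTK", "FGFR3",
                       "NF1", "RAF", "Other", "IDH")

#' Map classifier labels to frequency-matrix column names
#' @param label character vector of classifier labels.
#' @return character vector of subgroup column names (NA for DMG).
#' @export
subgroup_column <- function(label) {
  map <- c(G1_EGFR_amp = "EGFR_amp", G1_EGFR_mut = "EGFR_mut",
           G5_PDGFRA = "PDGFRA", G6_MultiRTK = "MultiRTK",
           G2_FGFR3 = "FGFR3", G3_NF1 = "NF1", G4_RAF = "RAF",
           G7_Other = "Other", IDH = "IDH", DMG = NA_character_)
  unname(map[label])
}

## RTK catalog: members of the 19 structural receptor tyrosine kinase classes
## considered when building the driver set.
GBM_RTK_GENES <- c(
  "EGFR", "ERBB2", "ERBB3", "ERBB4",
  "INSR", "IGF1R", "INSRR",
  "PDGFRA", "PDGFRB", "KIT", "KDR", "CSF1R", "FLT1", "FLT3", "FLT4",
  "FGFR1", "FGFR2", "FGFR3", "FGFR4",
  "MET", "MST1R",
  "NTRK1", "NTRK2", "NTRK3",
  "ALK", "LTK", "ROS1",
  "AXL", "MERTK", "TYRO3",
  "EPHA1", "EPHA2", "EPHA3", "EPHA4", "EPHA5", "EPHA6", "EPHA7", "EPHA8",
  "EPHB1", "EPHB2", "EPHB3", "EPHB4", "EPHB6",
  "RET", "DDR1", "DDR2", "TIE1", "TEK", "MUSK",
  "PTK7", "ROR1", "ROR2", "RYK", "AATK", "LMTK2", "LMTK3")

## Composite pathway gene sets (event kind per member is encoded in
## pathway_status(); amplification for CDK4/MDM2/MDM4/YEATS4, homozygous
## loss for CDKN2A, pathogenic small variant otherwise).
GBM_PATHWAY_SETS <- list(
  pi3k_mtor = c("PTEN", "PIK3CA", "PIK3R1", "TSC2", "MTOR"),
  g1_phase  = c("CDKN2A", "CDK4", "RB1"),
  tp53_path = c("TP53", "MDM2", "MDM4", "RPL5", "PPM1D"),
  mmr       = c("MSH6", "MSH5", "PMS2", "MLH3"),
  ddr_extra = c("ATM", "BRCA2"),
  swi_snf   = c("ARID1A", "ARID1B", "ARID2", "SMARCA1", "SMARCA4", "PBRM1"),
  chrm_mut  = c("DNMT3A", "TET2", "EZH2", "SUZ12", "ASXL1", "ASXL2",
                "KDM5C", "KDM6A", "KMT2C", "KMT2D", "CREBBP"),
  chrm_amp  = "YEATS4")

## Feature rows of the subgroup-by-feature frequency matrix, in display order.
GBM_FEATURES <- c("TERT", "PTEN", "PIK3CA", "PIK3R1", "PI3K_mTOR",
                  "CDKN2A_loss", "CDK4_amp", "RB1", "G1_phase",
                  "TP53", "MDM2_amp", "MDM4_amp", "RPL5", "PPM1D", "TP53_path",
                  "ATM", "BRCA2", "MMR", "DDR_path",
                  "STAG2", "SWI_SNF", "ChRm", "MGMT_methyl")

#' Reference subgroup sizes of the emulated cohort
#'
#' Numbers of cases per molecular subgroup used as the deterministic fixture
#' template: 87 IDH-wild-type cases with genomic data across eight subgroups,
#' 7 IDH-mutant cases with genomic data, 3 diffuse midline gliomas, and 4
#' IHC-only cases without sequencing (3 IDH-wild-type, 1 IDH-mutant), for a
#' 101-patient cohort.
#'
#' @return named integer vector.
#' @export
gbm_subgroup_sizes <- function() {
  c(EGFR_amp = 33L, EGFR_mut = 3L, PDGFRA = 7L, MultiRTK = 7L, FGFR3 = 5L,
    NF1 = 15L, RAF = 4L, Other = 13L, IDH = 7L, DMG = 3L,
    IDHwt_noNGS = 3L, IDHm_noNGS = 1L)
}

#' Reference per-subgroup alteration frequencies
#'
#' Percent of cases in each molecular subgroup carrying each alteration or
#' composite pathway alteration. These frequencies are the generator's
#' default study conditions; the deterministic fixture plants
#' `round(percent x n / 100)` events per cell.
#'
#' @return numeric matrix, features x subgroups (percent, 0-100).
#' @export
gbm_reference_frequencies <- function() {
  m <- rbind(
    #            EGFRa EGFRm PDGFRA MRTK FGFR3  NF1   RAF  Other  IDH
    TERT        = c(96.4, 100,  42.9, 100,   80, 73.3,  100, 81.8, 28.6),
    PTEN        = c(48.5, 33.3, 28.6, 71.4,  80, 46.7,   50, 69.2,    0),
    PIK3CA      = c(27.3,    0,    0, 14.3,   0, 13.3,    0, 15.4, 28.6),
    PIK3R1      = c( 9.1,    0, 28.6,    0,   0, 26.7,   25,  7.7,    0),
    PI3K_mTOR   = c(75.8, 33.3, 42.9, 71.4,  80,   80,   75,  100, 42.9),
    CDKN2A_loss = c(72.7,    0, 57.1, 42.9,  80,   60,   50, 15.4, 42.9),
    CDK4_amp    = c(   3,    0, 28.6, 14.3,   0,    0,    0, 46.2, 14.3),
    RB1         = c(   0,  100,    0, 28.6,  20,  6.7,    0, 30.8,    0),
    G1_phase    = c(75.8,  100, 85.7, 85.7, 100, 66.7,   50, 92.3, 57.1),
    TP53        = c(18.2, 66.7, 57.1, 57.1,  20, 33.3,    0, 53.8,  100),
    MDM2_amp    = c(   0,    0,    0, 14.3,  20,  6.7,    0, 15.4,    0),
    MDM4_amp    = c( 9.1,    0,    0,    0,   0,    0,    0,  7.7,    0),
    RPL5        = c( 6.1,    0,    0,    0,   0, 13.3,   25,    0,    0),
    PPM1D       = c(   0,    0, 14.3,    0,   0,    0,    0,    0,    0),
    TP53_path   = c(33.3, 66.7, 71.4, 71.4,  40, 53.3,   25, 69.2,  100),
    ATM         = c(12.1,    0, 42.9,    0,  20, 13.3,   25,    0,    0),
    BRCA2       = c( 9.1, 33.3, 14.3,    0,   0,    0,    0,    0, 28.6),
    MMR         = c(12.1,    0, 28.6, 14.3,  40,  6.7,    0,    0, 14.3),
    DDR_path    = c(27.3, 33.3, 71.4, 14.3,  60,   20,   25,    0, 42.9),
    STAG2       = c(15.2,    0, 14.3, 14.3,  20, 13.3,    0,    0,    0),
    SWI_SNF     = c(15.2,    0, 14.3, 28.6,   0,   20,   25,    0, 57.1),
    ChRm        = c(30.3,    0, 14.3, 57.1, 100,   20,    0, 38.5, 14.3),
    MGMT_methyl = c(43.3,    0,    0,   50,  50, 27.3,   50, 36.4, 42.9))
  colnames(m) <- GBM_SUBGROUP_COLS
  m
}

#' Printed reference totals over the 87 IDH-wild-type cases
#'
#' The reference whole-cohort percent for each feature, with the number of
#' printed decimal digits used when asserting reproduction. The PIK3CA and
#' STAG2 totals are not arithmetically consistent with their own subgroup
#' cells (the cells imply 16.1 and 11.5); `consistent` flags them.
#'
#' @return data.frame with columns feature, total, digits, consistent.
#' @export
gbm_reference_totals <- function() {
  data.frame(
    feature = GBM_FEATURES,
    total = c(85, 53, 18.4, 12.6, 75.9, 55.2, 11.5, 12.6, 79.3,
              33.3, 5.7, 4.6, 5.7, 1.1, 49.4, 12.6, 5.7, 11.5, 26.4,
              12.6, 13.8, 32.2, 36.1),
    digits = c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
               1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
               1L, 1L, 1L, 1L),
    consistent = !(GBM_FEATURES %in% c("PIK3CA", "STAG2")),
    stringsAsFactors = FALSE)
}

## Assessed-case denominators for the two partially covered assays in the
## deterministic fixture (TERT promoter/expression composite, MGMT assay).
## All other feature rows are assessed in every sequenced case.
GBM_FIXTURE_ASSAY_N <- list(
  TERT = c(EGFR_amp = 28L, EGFR_mut = 3L, PDGFRA = 7L, MultiRTK = 7L,
           FGFR3 = 5L, NF1 = 15L, RAF = 4L, Other = 11L, IDH = 7L),
  MGMT_methyl = c(EGFR_amp = 30L, EGFR_mut = 1L, PDGFRA = 7L, MultiRTK = 6L,
                  FGFR3 = 4L, NF1 = 11L, RAF = 2L, Other = 11L, IDH = 7L))

#' Reference per-subgroup survival medians (months)
#' @return named numeric vector of exponential survival medians per subgroup.
#' @export
gbm_survival_medians <- function() {
  c(EGFR_amp = 12, EGFR_mut = 6, PDGFRA = 12, MultiRTK = 7.5, FGFR3 = 20,
    NF1 = 6.7, RAF = 3.5, Other = 10, IDH = 30)
}

## round half away from zero (the rounding rule used for planted cell counts)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)
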