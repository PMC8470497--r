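## The deterministic fixture cohort.
##
## A fully reproducible, non-random 101-patient cohort whose per-subgroup
## alteration counts equal round(reference frequency x subgroup n) for every
## frequency-matrix cell, with the documented exclusivity structure:
## G1-phase events mutually exclusive except two heterozygous germline RB1
## point variants, TP53-pathway partner genes mutually exclusive, CDKN2A
## homozygous losses extended to CDKN2B except one FGFR3 case. TERT and
## MGMT are assessed in a per-subgroup subset of cases (partial assay
## coverage), giving the reduced denominators of the reference profile.

## lay `counts` member genes cyclically over composite positions `pos`;
## genes wrap onto already-covered positions (controlled overlap), and
## `filler` covers positions left empty when the member sum is short.
lay_members <- function(pos, counts, filler = NULL) {
  out <- list()
  p <- 0
  for (g in names(counts)) {
    k <- counts[[g]]
    if (k == 0) next
    sel <- ((p + seq_len(k) - 1) %% length(pos)) + 1
    out[[g]] <- pos[sel]
    p <- p + k
  }
  covered <- sort(unique(unlist(out)))
  if (!is.null(filler) && length(covered) < length(pos))
    out[[filler]] <- setdiff(pos, covered)
  out
}

fixture_histology <- list(
  EGFR_amp = c(rep("egfr", 18), rep("egfr_fgfr", 2), rep("pre_hgne", 3),
               "small_dark_reg", "hgne", "small_dark_reg", "hgne",
               "epithelioid", "small_dark_reg", "small_dark_irreg",
               "small_dark_irreg", "gliosarcoma", "fibroblastic"),
  EGFR_mut = c("small_dark_irreg", "small_dark_irreg", "epithelioid"),
  PDGFRA = c("pre_hgne", "pre_hgne", "hgne", "hgne", "hgne", "hgne",
             "small_dark_reg"),
  MultiRTK = c("gliosarcoma", "giant_cell", "giant_cell", "pleomorphic",
               "pleomorphic", "epithelioid", "epithelioid"),
  FGFR3 = c("egfr_fgfr", "egfr_fgfr", "egfr_fgfr", "fgfr_small",
            "fgfr_small"),
  NF1 = c(rep("fibroblastic", 8), "gliosarcoma", "gliosarcoma",
          "small_dark_reg", "small_dark_reg", "pre_hgne", "pleomorphic",
          "pleomorphic"),
  RAF = rep("small_dark_reg", 4),
  Other = c("pre_hgne", "epithelioid", rep("hgne", 6), "giant_cell",
            "epithelioid", "small_dark_irreg", "pre_hgne", "epithelioid"),
  IDH = c("egfr", "hgne", "pre_hgne", "pre_hgne", "small_dark_reg",
          "small_dark_reg", "fibroblastic"))

## per-subgroup deterministic age vectors (MultiRTK older with one outlier;
## IDH mean and median both exactly 42)
fixture_ages <- list(
  EGFR_amp = round(61 + 11 * sin(1:33)),
  EGFR_mut = c(58, 63, 66),
  PDGFRA = c(54, 58, 60, 62, 63, 66, 70),
  MultiRTK = c(60, 65, 67, 68, 73, 78, 79),
  FGFR3 = c(50, 56, 60, 64, 70),
  RAF = c(61, 64, 67, 70),
  NF1 = round(60 + 10 * sin(1:15)),
  Other = round(62 + 10 * sin(1:13)),
  IDH = c(36, 39, 42, 42, 45, 45, 45),
  DMG = c(28, 33, 41),
  IDHwt_noNGS = c(59, 64, 71),
  IDHm_noNGS = 42)

fixture_sex <- list(
  EGFR_amp = rep(c("M", "M", "F", "M", "F"), length.out = 33),  # 20M/13F
  EGFR_mut = c("M", "M", "F"),
  PDGFRA = c("M", "M", "M", "M", "M", "M", "F"),
  MultiRTK = c("M", "F", "M", "F", "M", "F", "M"),
  FGFR3 = c("F", "F", "M", "F", "F"),
  NF1 = rep(c("M", "M", "F", "M", "F"), 3),
  RAF = c("M", "F", "M", "F"),
  Other = rep(c("M", "F", "M"), length.out = 13),
  IDH = rep("F", 7), DMG = c("M", "F", "M"),
  IDHwt_noNGS = c("M", "M", "M"), IDHm_noNGS = "F")

fixture_ethnicity <- list(
  EGFR_amp = rep(c("White", "White", "White", "White", "Black", "White",
                   "Other"), length.out = 33),
  EGFR_mut = c("Black", "Black", "White"),
  PDGFRA = c(rep("White", 6), "Black"),
  MultiRTK = c(rep("White", 6), "Black"),
  FGFR3 = c(rep("White", 4), "Other"),
  NF1 = rep(c("White", "White", "White", "Black", "White"), 3),
  RAF = rep("White", 4),
  Other = rep(c("White", "White", "Black", "White", "Other"),
              length.out = 13),
  IDH = c("White", "White", "Black", "White", "Black", "White", "Black"),
  DMG = c("White", "Other", "White"),
  IDHwt_noNGS = rep("White", 3), IDHm_noNGS = "White")

fixture_location <- list(
  EGFR_amp = rep(c("frontal", "temporal", "parietal", "other_lobe",
                   "temporal", "frontal"), length.out = 33),
  EGFR_mut = c("temporal", "frontal", "parietal"),
  PDGFRA = c("midline", "midline", "frontal", "frontal", "frontal",
             "temporal", "parietal"),
  MultiRTK = c("frontal", "frontal", "frontal", "temporal", "parietal",
               "other_lobe", "temporal"),
  FGFR3 = c("temporal", "frontal", "parietal", "temporal", "other_lobe"),
  NF1 = c("midline", "corpus_callosum", "corpus_callosum",
          rep(c("temporal", "frontal", "parietal", "other_lobe"), 3)),
  RAF = c("frontal", "temporal", "other_lobe", "temporal"),
  Other = rep(c("temporal", "frontal", "parietal", "other_lobe"),
              length.out = 13),
  IDH = c("frontal", "frontal", "frontal", "temporal", "frontal",
          "parietal", "temporal"),
  DMG = c("midline", "midline", "midline"),
  IDHwt_noNGS = c("frontal", "temporal", "other_lobe"), IDHm_noNGS = "frontal")

## TERT assay design: promoter-mutated (m), overexpression-only (o),
## assessed wild-type with expression (w), unassessed without expression (u)
fixture_tert <- list(
  EGFR_amp = c(m = 26, o = 1, w = 1, u = 5),
  EGFR_mut = c(m = 3, o = 0, w = 0, u = 0),
  PDGFRA = c(m = 3, o = 0, w = 4, u = 0),
  MultiRTK = c(m = 7, o = 0, w = 0, u = 0),
  FGFR3 = c(m = 4, o = 0, w = 1, u = 0),
  NF1 = c(m = 10, o = 1, w = 4, u = 0),
  RAF = c(m = 4, o = 0, w = 0, u = 0),
  Other = c(m = 9, o = 0, w = 2, u = 2),
  IDH = c(m = 2, o = 0, w = 5, u = 0))

## MGMT assay design: positives, negatives, rest not assayed
fixture_mgmt <- list(
  EGFR_amp = c(pos = 13, neg = 17),
  EGFR_mut = c(pos = 0, neg = 1),
  PDGFRA = c(pos = 0, neg = 7),
  MultiRTK = c(pos = 3, neg = 3),
  FGFR3 = c(pos = 2, neg = 2),
  NF1 = c(pos = 3, neg = 8),
  RAF = c(pos = 1, neg = 1),
  Other = c(pos = 4, neg = 7),
  IDH = c(pos = 3, neg = 4))

## mean CDK6 fold and MKI67 (proliferation) fold per subgroup
fixture_cdk6 <- c(EGFR_amp = 6, EGFR_mut = 1.5, PDGFRA = 9, MultiRTK = 2,
                  FGFR3 = 6, NF1 = 3, RAF = 2.5, Other = 2, IDH = 1.2)
fixture_mki67 <- c(EGFR_amp = 6, EGFR_mut = 3, PDGFRA = 12, MultiRTK = 5,
                   FGFR3 = 5, NF1 = 4, RAF = 4, Other = 5, IDH = 2)

FIXTURE_EXPR_GENES <- c("EGFR", "PDGFRA", "KIT", "KDR", "MET", "FGFR3",
                        "FGFR2", "NTRK1", "ALK", "EPHA3", "EPHB2", "ERBB2",
                        "ERBB3", "ERBB4", "ROR1", "ROR2", "PTK7", "TERT",
                        "CDK6", "MKI67")

#' The deterministic fixture cohort
#'
#' Builds the checked-in-by-construction cohort emulating the 101-patient
#' study shape: 87 IDH-wild-type cases with sequencing data across the
#' eight molecular subgroups (33/3/7/7/5/15/4/13), 7 sequenced IDH-mutant
#' cases, 3 diffuse midline gliomas and 4 IHC-only cases. Driver profiles,
#' background alteration layouts, expression fold-changes, demographics,
#' survival and histology are all fixed; two successive calls return
#' identical objects.
#'
#' @return a `gbm_cohort` with a `truth` attribute (intended labels).
#' @export
deterministic_fixture <- function() {
  freq <- gbm_reference_frequencies()
  sizes <- gbm_subgroup_sizes()
  prefix <- c(EGFR_amp = "Ea", EGFR_mut = "Em", PDGFRA = "Pd",
              MultiRTK = "Mr", FGFR3 = "Fg", NF1 = "Nf", RAF = "Rf",
              Other = "Ot", IDH = "Id", DMG = "Dm",
              IDHwt_noNGS = "Nx", IDHm_noNGS = "Xm")
  label_of <- c(EGFR_amp = "G1_EGFR_amp", EGFR_mut = "G1_EGFR_mut",
                PDGFRA = "G5_PDGFRA", MultiRTK = "G6_MultiRTK",
                FGFR3 = "G2_FGFR3", NF1 = "G3_NF1", RAF = "G4_RAF",
                Other = "G7_Other", IDH = "IDH", DMG = "DMG",
                IDHwt_noNGS = "G7_Other", IDHm_noNGS = "IDH")
  medians <- gbm_survival_medians()

  variants <- list(); cn <- list(); fusions <- list(); clinical <- list()
  folds <- list()  # per case named fold vector (only cases with expression)
  truth <- list()

  addv <- function(id, gene, kind, path = "pathogenic", activating = FALSE,
                   germline = FALSE, hgvs = ".", secondary = FALSE) {
    variants[[length(variants) + 1]] <<- data.frame(
      case_id = id, gene = gene, kind = kind, pathogenicity = path,
      activating = activating, germline = germline, hgvs = hgvs,
      secondary_focus = secondary, stringsAsFactors = FALSE)
  }
  addcn <- function(id, gene, copy_number, loh = FALSE) {
    cn[[length(cn) + 1]] <<- data.frame(case_id = id, gene = gene,
                                        copy_number = copy_number, loh = loh,
                                        stringsAsFactors = FALSE)
  }
  addfu <- function(id, g5, g3, frame = "in_frame", path = "pathogenic") {
    fusions[[length(fusions) + 1]] <<- data.frame(
      case_id = id, gene5 = g5, gene3 = g3, frame = frame,
      pathogenicity = path, stringsAsFactors = FALSE)
  }

  for (grp in names(prefix)) {
    n <- sizes[[grp]]
    ids <- sprintf("%s%02d", prefix[[grp]], seq_len(n))
    has_ngs <- !(grp %in% c("IDHwt_noNGS", "IDHm_noNGS"))
    in_freq <- grp %in% colnames(freq)

    ## --- expression availability & base profile ---------------------------
    expr_idx <- integer()
    if (in_freq) {
      tert <- fixture_tert[[grp]]
      expr_idx <- seq_len(n - tert[["u"]])
      for (i in expr_idx) {
        f <- stats::setNames(rep(0.8 + 0.4 * (((i * 7) %% 10) / 10),
                                 length(FIXTURE_EXPR_GENES)),
                             FIXTURE_EXPR_GENES)
        f["PTK7"] <- 2.5; f["ROR1"] <- 3; f["ROR2"] <- 2
        f["KDR"] <- 1 + 3 * ((i %% 4) / 4)          # mild vascular signal
        f["CDK6"] <- fixture_cdk6[[grp]] + 0.4 * ((i %% 3) - 1)
        f["MKI67"] <- fixture_mki67[[grp]] + 0.5 * ((i %% 3) - 1)
        if (grp == "EGFR_amp")  # bimodal proliferation
          f["MKI67"] <- if (i %% 2) 8.5 else 3.5
        folds[[ids[i]]] <- f
      }
      ## TERT expression per assay design
      m <- tert[["m"]]; o <- tert[["o"]]; w <- tert[["w"]]
      for (i in expr_idx) {
        tf <- if (i <= m) 8
              else if (i <= m + o) 9       # activation by overexpression only
              else 1.2                      # assessed, wild-type, not activated
        folds[[ids[i]]]["TERT"] <- tf
      }
      for (i in seq_len(m)) addv(ids[i], "TERT", "promoter_mutation")
    }

    ## --- background alteration layouts ------------------------------------
    if (in_freq) {
      k <- function(feature) round_half_up(freq[feature, grp] * n / 100)
      ## G1 phase: sequential, mutually exclusive
      pos <- 1
      for (gset in c("CDKN2A_loss", "CDK4_amp", "RB1")) {
        kk <- k(gset)
        if (kk > 0) {
          idx <- pos:(pos + kk - 1)
          for (i in idx) {
            if (gset == "CDKN2A_loss") {
              addcn(ids[i], "CDKN2A", 0)
              ## homozygous losses extend to CDKN2B (one FGFR3 exception)
              if (!(grp == "FGFR3" && i == 1)) addcn(ids[i], "CDKN2B", 0)
            } else if (gset == "CDK4_amp") addcn(ids[i], "CDK4", 20)
            else addv(ids[i], "RB1", "truncating")
          }
          pos <- pos + kk
        }
      }
      ## two heterozygous germline RB1 point variants (exclusivity exceptions)
      if (grp == "EGFR_amp")
        for (i in 1:2) addv(ids[i], "RB1", "missense", path = "vus",
                            germline = TRUE, hgvs = "p.Arg320Cys")
      ## PI3K/mTOR at the head of the subgroup
      pi3k <- lay_members(seq_len(k("PI3K_mTOR")),
                          c(PTEN = k("PTEN"), PIK3CA = k("PIK3CA"),
                            PIK3R1 = k("PIK3R1")),
                          filler = if (grp == "IDH") "MTOR" else "TSC2")
      for (g in names(pi3k)) for (i in pi3k[[g]])
        addv(ids[i], g, "truncating")
      ## TP53 pathway at the tail; partner genes laid before TP53 so they
      ## stay mutually exclusive among themselves
      kc <- k("TP53_path")
      if (kc > 0) {
        tail_pos <- (n - kc + 1):n
        tp <- lay_members(tail_pos,
                          c(MDM2 = k("MDM2_amp"), MDM4 = k("MDM4_amp"),
                            RPL5 = k("RPL5"), PPM1D = k("PPM1D"),
                            TP53 = k("TP53")))
        for (g in names(tp)) for (i in tp[[g]]) {
          if (g %in% c("MDM2", "MDM4")) addcn(ids[i], g, 14)
          else addv(ids[i], g, "missense")
        }
      }
      ## DNA-damage response at the head
      ddr <- lay_members(seq_len(k("DDR_path")),
                         c(ATM = k("ATM"), BRCA2 = k("BRCA2"),
                           MSH6 = k("MMR")))
      for (g in names(ddr)) for (j in seq_along(ddr[[g]])) {
        gene <- if (g == "MSH6" && grp == "FGFR3" && j == 2) "PMS2" else g
        addv(ids[ddr[[g]][j]], gene, "truncating")
      }
      ## chromatin / cohesin
      for (i in seq_len(k("STAG2"))) addv(ids[i], "STAG2", "truncating")
      for (i in seq_len(k("SWI_SNF"))) {
        gene <- if (grp == "IDH" && i == 4) "SMARCA4" else "ARID1A"
        addv(ids[i], gene, "truncating")
      }
      kk <- k("ChRm")
      if (kk > 0) for (i in seq_len(kk)) {
        if (grp == "EGFR_amp" && i == 1) addcn(ids[i], "YEATS4", 11)
        else addv(ids[i], "DNMT3A", "missense")
      }
    }

    ## --- subgroup-defining drivers ----------------------------------------
    if (grp == "EGFR_amp") {
      cns <- 7 + (seq_len(n) * 5) %% 45
      cns[1] <- 20
      egfr_fold <- c(26, 72, 4.5, 10 + 2 * ((4:28) %% 20))
      for (i in seq_len(n)) {
        addcn(ids[i], "EGFR", cns[i])
        if (i %in% expr_idx) folds[[ids[i]]]["EGFR"] <- egfr_fold[i]
        ## vIII and kindred secondary variants on the majority of amplified
        ## cases; covers case 3, the amplified case without overexpression
        if (i %% 2 == 1 && i <= 21)
          addv(ids[i], "EGFR", "splice_variant", activating = TRUE,
               hgvs = "vIII")
        if (i == 2) addfu(ids[i], "EGFR", "SEPT14")
        if (i == 4) addfu(ids[i], "EGFR", "VOPP1")
        if (i == 6) addfu(ids[i], "SEC61G", "EGFR")
        if (i == 8) addfu(ids[i], "CTDSP2", "EGFR")
        if (i == 10) addv(ids[i], "EGFR", "truncating", activating = TRUE,
                          hgvs = "C-terminal deletion")
        if (i %in% c(12, 13, 14)) addv(ids[i], "ALK", "missense",
                                       path = "vus")
        if (i %in% c(5, 33))                   # multifocal secondary focus
          addv(ids[i], "EGFR", "missense", activating = TRUE,
               hgvs = "p.A289V", secondary = TRUE)
      }
    } else if (grp == "EGFR_mut") {
      for (i in seq_len(n)) {
        addv(ids[i], "EGFR", "missense", activating = TRUE,
             hgvs = "p.C620Y")
        folds[[ids[i]]]["EGFR"] <- c(2.5, 1.8, 3.0)[i]
        folds[[ids[i]]]["ERBB2"] <- 3.5
        addcn(ids[i], "RB1", 1, loh = TRUE)    # RB1 mutations with LOH
      }
    } else if (grp == "PDGFRA") {
      pd_cn <- c(10, 50, 30, 12, 9, 15)
      pd_fold <- c(4.9, 25.7, 16.8, 20, 12, 15, 21)
      for (i in seq_len(n)) {
        if (i <= 6) addcn(ids[i], "PDGFRA", pd_cn[i])
        folds[[ids[i]]]["PDGFRA"] <- pd_fold[i]
        if (i %in% c(4, 6)) {                  # contiguous 4q12 co-amplicon
          addcn(ids[i], "KIT", 9); addcn(ids[i], "KDR", 9)
          folds[[ids[i]]]["KIT"] <- 8; folds[[ids[i]]]["KDR"] <- 10
        }
        if (i %in% c(1, 7))                    # disulfide-bond cysteine hotspot
          addv(ids[i], "PDGFRA", "missense", activating = TRUE,
               hgvs = "p.Y288C")
        folds[[ids[i]]]["EPHB2"] <- 4
        folds[[ids[i]]]["ERBB3"] <- 3
      }
    } else if (grp == "MultiRTK") {
      for (i in 1:3) {                         # amplified, not overexpressed
        addcn(ids[i], "PDGFRA", c(9, 12, 8)[i])
        folds[[ids[i]]]["PDGFRA"] <- c(2.0, 3.1, 1.5)[i]
      }
      addcn(ids[1], "MET", 4); folds[[ids[1]]]["MET"] <- 28
      folds[[ids[2]]]["KIT"] <- 12
      addcn(ids[4], "MET", 12); folds[[ids[4]]]["MET"] <- 45
      addcn(ids[5], "MET", 15); folds[[ids[5]]]["MET"] <- 52
      addfu(ids[6], "LMNA", "NTRK1"); folds[[ids[6]]]["EPHA3"] <- 8
      addcn(ids[7], "EGFR", 9); folds[[ids[7]]]["EGFR"] <- 15
      addcn(ids[7], "MET", 5); folds[[ids[7]]]["MET"] <- 11
    } else if (grp == "FGFR3") {
      fg_fold <- c(15, 22, 30, 18, 25)
      for (i in seq_len(n)) {
        if (i <= 4) addfu(ids[i], "FGFR3", "TACC3")
        else addv(ids[i], "FGFR3", "missense", activating = TRUE,
                  hgvs = "p.S249C")
        folds[[ids[i]]]["FGFR3"] <- fg_fold[i]
      }
    } else if (grp == "NF1") {
      for (i in seq_len(n)) {
        if (i <= 6) { addv(ids[i], "NF1", "truncating")
                      addcn(ids[i], "NF1", 1, loh = TRUE) }
        else if (i <= 10) { addv(ids[i], "NF1", "truncating")
                            addv(ids[i], "NF1", "frameshift") }
        else if (i == 11) { addfu(ids[i], "NF1", "RNF135",
                                  frame = "frameshift")
                            addv(ids[i], "NF1", "truncating") }
        else if (i == 12) { addfu(ids[i], "NF1", "PSMD11",
                                  frame = "frameshift")
                            addcn(ids[i], "NF1", 1, loh = TRUE) }
        else if (i <= 14) { addv(ids[i], "NF1", "truncating",
                                 germline = TRUE)  # syndromic
                            addv(ids[i], "NF1", "missense") }
        else addv(ids[i], "NF1", "truncating")     # single-hit case
        if (i <= 3 && ids[i] %in% names(folds)) folds[[ids[i]]]["ALK"] <- 6 + i
      }
    } else if (grp == "RAF") {
      for (i in 1:3) addv(ids[i], "BRAF", "missense", activating = TRUE,
                          hgvs = "p.V600E")
      addv(ids[4], "RAF1", "missense", activating = TRUE, hgvs = "p.S257L")
      addcn(ids[4], "RAF1", 8)
      folds[[ids[1]]]["NTRK1"] <- 6; folds[[ids[2]]]["NTRK1"] <- 7
    } else if (grp == "IDH" || grp == "DMG") {
      for (i in seq_len(n)) {
        if (grp == "IDH") addv(ids[i], "IDH1", "missense", hgvs = "p.R132H")
        else addv(ids[i], "H3-3A", "missense", hgvs = "p.K28M")
        if (grp == "IDH") folds[[ids[i]]]["ERBB4"] <- 3.5
      }
      if (grp == "IDH") { addcn(ids[1], "FGFR2", 12)
                          folds[[ids[1]]]["FGFR2"] <- 30 }
    }
    ## "Other", IDHwt_noNGS, IDHm_noNGS: no drivers

    ## --- clinical rows ----------------------------------------------------
    med <- if (grp %in% names(medians)) medians[[grp]]
           else if (grp == "IDHm_noNGS") medians[["IDH"]]
           else if (grp == "DMG") 6 else 10
    surv <- round(stats::qexp((seq_len(n) - 0.5) / n,
                              rate = log(2) / med), 1)
    event <- rep(TRUE, n)
    cens <- which(seq_len(n) %% 10 == 0)
    event[cens] <- FALSE
    surv[cens] <- round(surv[cens] * 0.6, 1)
    if (grp == "FGFR3") surv[n] <- 84                 # 7-year survivor
    if (grp == "EGFR_amp") surv[which.max(surv)] <- 84
    mg <- rep(NA_real_, n)
    if (in_freq) {
      mm <- fixture_mgmt[[grp]]
      if (mm[["pos"]] > 0)
        mg[seq_len(mm[["pos"]])] <- c(5, 5.3, 8, 12, 16, 20, 24, 9, 11,
                                      14, 18, 22, 26)[seq_len(mm[["pos"]])]
      if (mm[["neg"]] > 0)
        mg[mm[["pos"]] + seq_len(mm[["neg"]])] <-
          rep(c(0.5, 1.4, 2.2, 3.1, 4.2), length.out = mm[["neg"]])
    }
    histo <- if (in_freq) fixture_histology[[grp]] else rep("unknown", n)
    idh_ihc <- if (grp %in% c("IDH", "IDHm_noNGS")) "positive"
               else if (grp == "DMG") "missing" else "negative"
    h3_ihc <- if (grp == "DMG") "positive" else "negative"
    gfap <- rep("high", n)
    if (grp == "MultiRTK") gfap[1:4] <- "low"
    if (grp == "Other") gfap[1:9] <- rep(c("low", "absent"), length.out = 9)
    if (grp == "RAF") gfap[1:3] <- "low"
    clinical[[length(clinical) + 1]] <- data.frame(
      case_id = ids, age = fixture_ages[[grp]], sex = fixture_sex[[grp]],
      ethnicity = fixture_ethnicity[[grp]], location = fixture_location[[grp]],
      survival_months = surv, event_observed = event,
      idh1_r132h = idh_ihc, h3_k27m = h3_ihc, gfap = gfap,
      p53 = ifelse(seq_len(n) %% 2 == 0, 2L, 1L),
      ki67 = round(pmin(80, 5 * fixture_mki67[[if (in_freq) grp else "IDH"]] +
                          seq_len(n) %% 7)),
      histologic_pattern = histo, mgmt_value = mg,
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- data.frame(case_id = ids,
                                             intended_label = label_of[[grp]],
                                             stringsAsFactors = FALSE)
  }

  clinical <- do.call(rbind, clinical)
  variants <- do.call(rbind, variants)
  cn <- do.call(rbind, cn)
  fusions <- do.call(rbind, fusions)

  ## expression counts: fold x control mean (controls 950/1000/1050),
  ## plus genes exercising the count / pseudogene / chromosome-Y filters
  genes <- c(FIXTURE_EXPR_GENES, "LOWCOUNT1", "PSEUDO1", "RPS4Y1")
  samples <- names(folds)
  expr <- matrix(0, length(genes), length(samples) + 3,
                 dimnames = list(genes, c(samples, paste0("control:LGG", 1:3))))
  for (s in samples) expr[FIXTURE_EXPR_GENES, s] <-
    round(folds[[s]][FIXTURE_EXPR_GENES] * 1000)
  expr["LOWCOUNT1", samples] <- 499
  expr["PSEUDO1", samples] <- 2000
  expr["RPS4Y1", samples] <- 3000
  expr[, paste0("control:LGG", 1:3)] <- c(rep(950, length(genes)),
                                          rep(1000, length(genes)),
                                          rep(1050, length(genes)))
  expr[c("LOWCOUNT1", "PSEUDO1", "RPS4Y1"),
       paste0("control:LGG", 1:3)] <- 300
  annotation <- data.frame(
    gene = genes, is_pseudogene = genes == "PSEUDO1",
    chromosome = ifelse(genes == "RPS4Y1", "Y", "autosome"),
    stringsAsFactors = FALSE)

  co <- new_cohort(clinical, variants, cn, fusions, expr, annotation,
                   name = "deterministic_fixture")
  attr(co, "truth") <- do.call(rbind, truth)
  co
}
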