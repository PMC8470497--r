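## Mutually exclusive molecular subgrouping (DMG / IDH / G1-G7).

#' Classifier configuration
#'
#' Tunable parameters of the rule-based subgroup classifier.
#'
#' @param rtk_genes RTK catalog scanned for driver evidence.
#' @param cn_threshold amplification cutoff (copy number), default 7.
#' @param fold_threshold overexpression cutoff (fold), default 5.
#' @param high_fold very high overexpression cutoff that by itself counts as
#'   driver evidence for `high_fold_genes`, default 10.
#' @param high_fold_genes genes for which overexpression without
#'   amplification is accepted as a driver; default `MET` only.
#' @param mgmt_threshold MGMT methylation positivity cutoff, default 5.
#' @param locus_groups list of amplicon gene groups collapsed to their first
#'   member when co-amplified (4q12 PDGFRA/KIT/KDR by default).
#' @return list of class `glioclass_config` with a stable `hash`.
#' @export
classifier_config <- function(rtk_genes = GBM_RTK_GENES, cn_threshold = 7,
                              fold_threshold = 5, high_fold = 10,
                              high_fold_genes = "MET", mgmt_threshold = 5,
                              locus_groups = list(c("PDGFRA", "KIT", "KDR"))) {
  cfg <- list(rtk_genes = rtk_genes, cn_threshold = cn_threshold,
              fold_threshold = fold_threshold, high_fold = high_fold,
              high_fold_genes = high_fold_genes,
              mgmt_threshold = mgmt_threshold, locus_groups = locus_groups)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "glioclass_config"
  cfg
}

## md5 of the deparsed configuration, recorded in every report
config_hash <- function(cfg) {
  cfg$hash <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}

## RTK driver set of one case: gene -> evidence kind
rtk_driver_set <- function(calls, config) {
  if (nrow(calls) == 0L) return(character(0))
  r <- calls[calls$gene %in% config$rtk_genes, , drop = FALSE]
  if (nrow(r) == 0L) return(character(0))
  amp_drv <- r$amplified & (is.na(r$overexpressed) | r$overexpressed)
  mut_drv <- r$activating_mutation
  fus_drv <- r$pathogenic_fusion
  fold_drv <- r$gene %in% config$high_fold_genes & !r$amplified &
    !is.na(r$fold) & r$fold >= config$high_fold
  drv <- amp_drv | mut_drv | fus_drv | fold_drv
  ev <- ifelse(mut_drv, "activating_mutation",
        ifelse(fus_drv, "pathogenic_fusion",
        ifelse(amp_drv, "amplification", "high_overexpression")))
  d <- stats::setNames(ev[drv], r$gene[drv])
  ## collapse co-amplified amplicon neighbours (e.g. PDGFRA/KIT/KDR) to the
  ## locus representative when their evidence is amplification-only
  for (grp in config$locus_groups) {
    present <- intersect(grp, names(d))
    if (length(present) > 1 && present[1] == grp[1]) {
      secondary <- setdiff(present, grp[1])
      amp_only <- secondary[d[secondary] == "amplification" &
        !(secondary %in% r$gene[mut_drv | fus_drv | fold_drv])]
      d <- d[!(names(d) %in% amp_only)]
    }
  }
  d
}

#' Classify one case
#'
#' Applies the ordered rule set: H3 K27M positivity triages to DMG; IDH1
#' R132H IHC or pathogenic IDH1/IDH2 variants to IDH; then the RTK driver
#' set decides between the RTK subgroups (single EGFR / FGFR3 / PDGFRA
#' driver, or Multi-RTK for multiple drivers, PDGFRA amplification without
#' overexpression, or a lone non-canonical RTK driver); NF1 inactivation and
#' BRAF/RAF1 activation are considered only when no RTK driver is present;
#' everything else is Other.
#'
#' @param cohort a `gbm_cohort`.
#' @param id case id.
#' @param config a [classifier_config()].
#' @param calls optional precomputed [gene_calls()] for the case.
#' @return list of class `subgroup_call`: `label`, `drivers` (named evidence
#'   vector), `rationale` (rule ids fired), `flags`.
#' @export
classify_case <- function(cohort, id, config = classifier_config(),
                          calls = NULL) {
  cl <- cohort$clinical[cohort$clinical$case_id == id, , drop = FALSE]
  if (nrow(cl) != 1L) stop("unknown case_id: ", id)
  if (is.null(calls)) calls <- gene_calls(cohort, id, config)
  flags <- character()
  rationale <- character()

  idh_pos <- cl$idh1_r132h %in% "positive"
  h3_pos <- cl$h3_k27m %in% "positive"
  if (idh_pos && h3_pos)
    stop("contradictory IHC for case ", id, ": IDH1 R132H and H3 K27M both positive")
  if (h3_pos)
    return(new_call("DMG", character(), "R0_h3k27m", flags))
  idh_var <- any(calls$gene %in% c("IDH1", "IDH2") &
                   calls$n_pathogenic_small > 0)
  if (idh_pos || idh_var)
    return(new_call("IDH", character(), "R1_idh", flags))

  no_data <- nrow(calls) == 0L && !has_genomic_data(cohort, id)
  if (no_data) {
    warning("case ", id, " has no molecular data; assigned G7_Other")
    return(new_call("G7_Other", character(), "R7_default",
                    c(flags, "no_molecular_data")))
  }

  D <- rtk_driver_set(calls, config)
  rationale <- c(rationale, "R2_driver_set")

  ## PDGFRA amplified with expression known and below threshold, and no
  ## functional PDGFRA driver evidence: routed to Multi-RTK
  pdgfra <- calls[calls$gene == "PDGFRA", , drop = FALSE]
  pdgfra_amp_silent <- nrow(pdgfra) == 1L && pdgfra$amplified &&
    identical(pdgfra$overexpressed, FALSE) &&
    !pdgfra$activating_mutation && !pdgfra$pathogenic_fusion
  canonical <- c("EGFR", "FGFR3", "PDGFRA")

  nf1 <- calls[calls$gene == "NF1", , drop = FALSE]
  nf1_path <- nrow(nf1) == 1L &&
    (nf1$biallelic_loss || nf1$n_pathogenic_small > 0 ||
       nf1$frameshift_fusion ||
       (nf1$germline_pathogenic && (nf1$loh || nf1$n_pathogenic_small > 0)))
  raf <- calls[calls$gene %in% c("BRAF", "RAF1"), , drop = FALSE]
  raf_act <- nrow(raf) > 0 && any(raf$activating_mutation)

  label <- NULL
  if (length(D) >= 2) {
    label <- "G6_MultiRTK"; rationale <- c(rationale, "R3_multi_rtk")
  } else if (pdgfra_amp_silent) {
    label <- "G6_MultiRTK"; rationale <- c(rationale, "R3_pdgfra_amp_no_overexpr")
    if (!("PDGFRA" %in% names(D)))
      D <- c(D, PDGFRA = "amplification_without_overexpression")
  } else if (length(D) == 1 && !(names(D) %in% canonical)) {
    label <- "G6_MultiRTK"; rationale <- c(rationale, "R3_noncanonical_rtk")
  } else if (length(D) == 1 && names(D) == "EGFR") {
    egfr <- calls[calls$gene == "EGFR", , drop = FALSE]
    if (egfr$amplified) {
      label <- "G1_EGFR_amp"; rationale <- c(rationale, "R4_egfr_amp")
    } else {
      label <- "G1_EGFR_mut"; rationale <- c(rationale, "R4_egfr_mut")
    }
  } else if (length(D) == 1 && names(D) == "FGFR3") {
    label <- "G2_FGFR3"; rationale <- c(rationale, "R4_fgfr3")
  } else if (length(D) == 1 && names(D) == "PDGFRA") {
    label <- "G5_PDGFRA"; rationale <- c(rationale, "R4_pdgfra")
  } else if (nf1_path) {
    label <- "G3_NF1"; rationale <- c(rationale, "R5_nf1")
    D <- c(D, NF1 = if (nf1$biallelic_loss) "biallelic_inactivation"
                    else "monoallelic_pathogenic")
    if (!nf1$biallelic_loss) flags <- c(flags, "monoallelic")
    if (nf1$germline_pathogenic) flags <- c(flags, "syndromic")
  } else if (raf_act) {
    label <- "G4_RAF"; rationale <- c(rationale, "R6_raf")
    g <- raf$gene[raf$activating_mutation][1]
    D <- c(D, stats::setNames("activating_mutation", g))
  } else {
    label <- "G7_Other"; rationale <- c(rationale, "R7_default")
  }
  ## exclusivity conflict audit: RTK label while NF1/RAF evidence also present
  if (startsWith(label, "G1_") || label %in%
        c("G2_FGFR3", "G5_PDGFRA", "G6_MultiRTK")) {
    if (nf1_path || raf_act) flags <- c(flags, "conflict")
  }
  new_call(label, D, rationale, flags)
}

new_call <- function(label, drivers, rationale, flags) {
  structure(list(label = label, drivers = drivers, rationale = rationale,
                 flags = flags), class = "subgroup_call")
}

#' @export
print.subgroup_call <- function(x, ...) {
  drv <- if (length(x$drivers))
    paste(names(x$drivers), x$drivers, sep = ":", collapse = "; ") else "none"
  cat(sprintf("<subgroup_call> %s\n  drivers: %s\n  rules: %s\n", x$label, drv,
              paste(x$rationale, collapse = " -> ")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Classify every case of a cohort
#'
#' @param cohort a `gbm_cohort`.
#' @param config a [classifier_config()].
#' @param calls optional precomputed [cohort_calls()].
#' @param verbose log per-label counts.
#' @return data.frame: case_id, label, drivers (semicolon-joined
#'   gene:evidence), rationale, flags.
#' @export
classify_cohort <- function(cohort, config = classifier_config(),
                            calls = NULL, verbose = FALSE) {
  if (is.null(calls)) calls <- cohort_calls(cohort, config)
  ids <- case_ids(cohort)
  res <- lapply(ids, function(i) {
    sc <- tryCatch(classify_case(cohort, i, config, calls = calls[[i]]),
                   error = function(e)
                     stop("case ", i, ": ", conditionMessage(e), call. = FALSE))
    data.frame(case_id = i, label = sc$label,
               drivers = paste(names(sc$drivers), sc$drivers, sep = ":",
                               collapse = ";"),
               rationale = paste(sc$rationale, collapse = ";"),
               flags = paste(sc$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (verbose) {
    tab <- table(factor(out$label, levels = GBM_LABELS))
    message("subgroup counts: ",
            paste(names(tab), tab, sep = "=", collapse = " "))
  }
  out
}

#' Cohort-level classification summary
#'
#' Subgroup counts and the headline fractions of the classification, over
#' IDH-wild-type cases with genomic data (DMG and sequencing-free cases are
#' excluded from every denominator).
#'
#' @param cohort a `gbm_cohort`.
#' @param subgroup_calls result of [classify_cohort()].
#' @param calls optional precomputed [cohort_calls()] (used for the
#'   amplification-within-subgroup fractions).
#' @param config a [classifier_config()].
#' @return list with `counts` (per label), `n_idh_wt`, and percents:
#'   `rtk_pct`, `egfr_pct`, `mapk_pct`, `other_pct`, `pdgfra_pct`,
#'   `multirtk_pct`, `egfr_amp_within_egfr_pct`,
#'   `pdgfra_amp_within_pdgfra_pct`.
#' @export
classification_summary <- function(cohort, subgroup_calls, calls = NULL,
                                   config = classifier_config()) {
  if (is.null(calls)) calls <- cohort_calls(cohort, config)
  genomic <- has_genomic_data(cohort, subgroup_calls$case_id)
  sc <- subgroup_calls[genomic, , drop = FALSE]
  wt <- sc[!(sc$label %in% c("DMG", "IDH")), , drop = FALSE]
  n <- nrow(wt)
  counts <- table(factor(sc$label, levels = GBM_LABELS))
  pct <- function(k) 100 * k / n
  rtk <- sum(wt$label %in% c("G1_EGFR_amp", "G1_EGFR_mut", "G2_FGFR3",
                             "G5_PDGFRA", "G6_MultiRTK"))
  egfr <- sum(wt$label %in% c("G1_EGFR_amp", "G1_EGFR_mut"))
  mapk <- rtk + sum(wt$label %in% c("G3_NF1", "G4_RAF"))
  amp_call <- function(ids, gene) {
    vapply(ids, function(i) {
      g <- calls[[i]]
      any(g$gene == gene & g$amplified)
    }, logical(1))
  }
  egfr_ids <- wt$case_id[wt$label %in% c("G1_EGFR_amp", "G1_EGFR_mut")]
  pdgfra_ids <- wt$case_id[wt$label == "G5_PDGFRA"]
  list(counts = counts, n_idh_wt = n,
       rtk_pct = pct(rtk), egfr_pct = pct(egfr), mapk_pct = pct(mapk),
       other_pct = pct(sum(wt$label == "G7_Other")),
       pdgfra_pct = pct(sum(wt$label == "G5_PDGFRA")),
       multirtk_pct = pct(sum(wt$label == "G6_MultiRTK")),
       egfr_amp_within_egfr_pct =
         100 * mean(amp_call(egfr_ids, "EGFR")),
       pdgfra_amp_within_pdgfra_pct =
         100 * mean(amp_call(pdgfra_ids, "PDGFRA")))
}
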