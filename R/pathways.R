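## Composite pathway statuses and the subgroup-by-feature frequency matrix.

path_mut <- function(calls, genes) {
  any(calls$gene %in% genes & calls$n_pathogenic_small > 0)
}
path_amp <- function(calls, genes) any(calls$gene %in% genes & calls$amplified)

#' Full per-case feature status vector
#'
#' One logical per frequency-matrix feature row: single-gene rows are
#' pathogenic/likely-pathogenic small variants (amplification for
#' CDK4/MDM2/MDM4, homozygous loss for CDKN2A), composite rows are the OR
#' over their gene set, TERT is the composite telomerase-activation call and
#' MGMT the methylation call. `NA` marks an unassessed feature (TERT without
#' promoter coverage or expression; MGMT without assay).
#'
#' @param cohort a `gbm_cohort`.
#' @param id case id.
#' @param calls optional precomputed [gene_calls()].
#' @param config a [classifier_config()].
#' @return named logical vector over the feature rows.
#' @export
case_feature_status <- function(cohort, id, calls = NULL,
                                config = classifier_config()) {
  if (is.null(calls)) calls <- gene_calls(cohort, id, config)
  cl <- cohort$clinical[cohort$clinical$case_id == id, , drop = FALSE]
  fold <- case_fold(cohort, id)
  tert <- calls[calls$gene == "TERT", , drop = FALSE]
  tert_mut <- nrow(tert) == 1L && tert$promoter_mutation
  tert_fold <- if (!is.null(fold) && "TERT" %in% names(fold))
    unname(fold["TERT"]) else NA_real_
  sets <- GBM_PATHWAY_SETS
  mmr <- path_mut(calls, sets$mmr)
  status <- c(
    TERT = call_tert_activation(tert_mut, tert_fold, config$fold_threshold),
    PTEN = path_mut(calls, "PTEN"),
    PIK3CA = path_mut(calls, "PIK3CA"),
    PIK3R1 = path_mut(calls, "PIK3R1"),
    PI3K_mTOR = path_mut(calls, sets$pi3k_mtor),
    CDKN2A_loss = any(calls$gene == "CDKN2A" & calls$homozygous_loss),
    CDK4_amp = path_amp(calls, "CDK4"),
    RB1 = path_mut(calls, "RB1"),
    G1_phase = any(calls$gene == "CDKN2A" & calls$homozygous_loss) ||
      path_amp(calls, "CDK4") || path_mut(calls, "RB1"),
    TP53 = path_mut(calls, "TP53"),
    MDM2_amp = path_amp(calls, "MDM2"),
    MDM4_amp = path_amp(calls, "MDM4"),
    RPL5 = path_mut(calls, "RPL5"),
    PPM1D = path_mut(calls, "PPM1D"),
    TP53_path = path_mut(calls, c("TP53", "RPL5", "PPM1D")) ||
      path_amp(calls, c("MDM2", "MDM4")),
    ATM = path_mut(calls, "ATM"),
    BRCA2 = path_mut(calls, "BRCA2"),
    MMR = mmr,
    DDR_path = path_mut(calls, sets$ddr_extra) || mmr,
    STAG2 = path_mut(calls, "STAG2"),
    SWI_SNF = path_mut(calls, sets$swi_snf),
    ChRm = path_mut(calls, sets$chrm_mut) || path_amp(calls, sets$chrm_amp),
    MGMT_methyl = c(positive = TRUE, negative = FALSE,
                    unknown = NA)[call_mgmt_methylated(
                      cl$mgmt_value, config$mgmt_threshold)])
  names(status) <- GBM_FEATURES
  status
}

#' Composite pathway status of one case
#'
#' @inheritParams case_feature_status
#' @return list of class `pathway_status`: tert_path, pi3k_mtor, g1_phase,
#'   tp53_path, ddr_path, mmr, swi_snf, other_chrm (logicals) and mgmt
#'   (positive/negative/unknown).
#' @export
pathway_status <- function(cohort, id, calls = NULL,
                           config = classifier_config()) {
  s <- case_feature_status(cohort, id, calls, config)
  structure(list(tert_path = unname(s["TERT"]),
                 pi3k_mtor = unname(s["PI3K_mTOR"]),
                 g1_phase = unname(s["G1_phase"]),
                 tp53_path = unname(s["TP53_path"]),
                 ddr_path = unname(s["DDR_path"]),
                 mmr = unname(s["MMR"]),
                 swi_snf = unname(s["SWI_SNF"]),
                 other_chrm = unname(s["ChRm"]),
                 mgmt = call_mgmt_methylated(
                   cohort$clinical$mgmt_value[
                     cohort$clinical$case_id == id], config$mgmt_threshold)),
            class = "pathway_status")
}

#' Subgroup-by-feature frequency matrix
#'
#' Percent of cases in each molecular subgroup carrying each alteration,
#' computed over cases with genomic data. The per-cell denominator is the
#' number of cases in the subgroup with the feature assessed (non-missing);
#' the Total column covers IDH-wild-type cases only. Columns for subgroups
#' absent from the cohort are reported as `NA`.
#'
#' @param cohort a `gbm_cohort`.
#' @param subgroup_calls result of [classify_cohort()].
#' @param calls optional precomputed [cohort_calls()].
#' @param config a [classifier_config()].
#' @return list of class `cohort_summary`: `matrix` (percent, features x
#'   subgroups + Total), `counts` and `denominators` (same shape), `n`
#'   (cases per subgroup).
#' @export
frequency_matrix <- function(cohort, subgroup_calls, calls = NULL,
                             config = classifier_config()) {
  if (is.null(calls)) calls <- cohort_calls(cohort, config)
  genomic <- has_genomic_data(cohort, subgroup_calls$case_id)
  sc <- subgroup_calls[genomic & subgroup_calls$label != "DMG", , drop = FALSE]
  sc$col <- subgroup_column(sc$label)
  status <- vapply(sc$case_id, function(i)
    case_feature_status(cohort, i, calls[[i]], config),
    logical(length(GBM_FEATURES)))
  cols <- c(GBM_SUBGROUP_COLS, "Total")
  k <- d <- matrix(NA_real_, length(GBM_FEATURES), length(cols),
                   dimnames = list(GBM_FEATURES, cols))
  n <- stats::setNames(integer(length(GBM_SUBGROUP_COLS)), GBM_SUBGROUP_COLS)
  for (g in GBM_SUBGROUP_COLS) {
    in_g <- sc$col == g
    n[g] <- sum(in_g)
    if (!n[g]) next  # empty subgroup: row cells stay missing, not 0
    sub <- status[, in_g, drop = FALSE]
    k[, g] <- rowSums(sub, na.rm = TRUE)
    d[, g] <- rowSums(!is.na(sub))
  }
  wt <- setdiff(GBM_SUBGROUP_COLS, "IDH")
  k[, "Total"] <- rowSums(k[, wt, drop = FALSE], na.rm = TRUE)
  d[, "Total"] <- rowSums(d[, wt, drop = FALSE], na.rm = TRUE)
  pct <- 100 * k / ifelse(d == 0, NA, d)
  structure(list(matrix = pct, counts = k, denominators = d, n = n),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> subgroup n:",
      paste(names(x$n), x$n, sep = "=", collapse = " "), "\n")
  print(round(x$matrix, 1))
  invisible(x)
}

#' Export a frequency matrix as TSV
#'
#' Features as rows, subgroups as columns, percents rounded to one decimal.
#'
#' @param summary a `cohort_summary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(summary, path) {
  df <- data.frame(feature = rownames(summary$matrix),
                   round(summary$matrix, 1), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Audit mutual exclusivity of the cell-cycle G1-phase events
#'
#' Counts cases carrying more than one of: CDKN2A homozygous loss, CDK4
#' amplification, or an RB1 point variant (any pathogenicity, somatic or
#' germline). The emulated cohort carries exactly two such exceptions, both
#' heterozygous germline RB1 point variants.
#'
#' @param cohort a `gbm_cohort`.
#' @param calls optional precomputed [cohort_calls()].
#' @param config a [classifier_config()].
#' @return character vector of case ids violating exclusivity.
#' @export
audit_g1_exclusivity <- function(cohort, calls = NULL,
                                 config = classifier_config()) {
  if (is.null(calls)) calls <- cohort_calls(cohort, config)
  ids <- case_ids(cohort)
  bad <- vapply(ids, function(i) {
    g <- calls[[i]]
    rb1_point <- any(cohort$variants$case_id == i &
                       cohort$variants$gene == "RB1" &
                       cohort$variants$kind %in%
                         c("missense", "truncating", "frameshift",
                           "splice_variant"))
    sum(any(g$gene == "CDKN2A" & g$homozygous_loss),
        any(g$gene == "CDK4" & g$amplified), rb1_point) > 1
  }, logical(1))
  ids[bad]
}
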