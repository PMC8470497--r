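## Histologic pattern-to-cluster mapping and histologic-molecular tests.

#' Histology configuration: pattern-to-cluster mapping
#'
#' Maps each of the 12 histologic patterns to one of the five morphology
#' clusters (EGFR-like, Small neuronal-like, Anaplastic, Spindle,
#' Epithelioid). Assignments not fixed by the morphology descriptions are
#' tagged `inferred` and can be overridden.
#'
#' @param overrides named character vector of pattern -> cluster overrides.
#' @return list of class `histology_config` with `pattern_to_cluster` and
#'   `inferred` (patterns whose default is an inference).
#' @export
histology_config <- function(overrides = NULL) {
  map <- c(egfr = "EGFR_like", egfr_fgfr = "EGFR_like",
           fgfr_small = "Small_neuronal", small_dark_reg = "Small_neuronal",
           pre_hgne = "Small_neuronal", hgne = "Anaplastic",
           small_dark_irreg = "Anaplastic", pleomorphic = "Anaplastic",
           fibroblastic = "Spindle", gliosarcoma = "Spindle",
           giant_cell = "Epithelioid", epithelioid = "Epithelioid")
  inferred <- c("small_dark_irreg", "pleomorphic")
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), GBM_PATTERNS)
    if (length(bad)) stop("unknown pattern in overrides: ",
                          paste(bad, collapse = ", "))
    check_enum(overrides, GBM_HISTO_CLUSTERS, "histologic cluster")
    map[names(overrides)] <- overrides
  }
  stopifnot(setequal(names(map), GBM_PATTERNS))
  structure(list(pattern_to_cluster = map, inferred = inferred),
            class = "histology_config")
}

#' Histologic cluster of a pattern
#'
#' @param pattern one of the 12 pattern names (vectorized); `"unknown"`
#'   yields `NA`.
#' @param config a [histology_config()].
#' @return cluster name(s).
#' @export
assign_histologic_cluster <- function(pattern, config = histology_config()) {
  bad <- setdiff(pattern, c(GBM_PATTERNS, "unknown", NA))
  if (length(bad)) stop("unknown histologic pattern: ",
                        paste(bad, collapse = ", "))
  out <- unname(config$pattern_to_cluster[pattern])
  out[pattern %in% c("unknown", NA)] <- NA_character_
  out
}

#' Histologic-molecular association tests
#'
#' For every (histologic cluster, molecular feature) pair, a 2x2 table of
#' cluster membership against feature status over IDH-wild-type cases with
#' known histology, with a two-sided Fisher exact test. Clusters absent
#' from the cohort are skipped with a note.
#'
#' @param cohort a `gbm_cohort`.
#' @param subgroup_calls result of [classify_cohort()].
#' @param features feature rows to test (default the G1-phase and TP53
#'   features highlighted by the morphology analysis).
#' @param calls optional precomputed [cohort_calls()].
#' @param config a [classifier_config()].
#' @param histo_config a [histology_config()].
#' @return data.frame: cluster, feature, the 2x2 cell counts, odds ratio and
#'   Fisher p-value.
#' @export
histo_molecular_association <- function(cohort, subgroup_calls,
                                        features = c("CDKN2A_loss",
                                                     "CDK4_amp", "RB1",
                                                     "TP53"),
                                        calls = NULL,
                                        config = classifier_config(),
                                        histo_config = histology_config()) {
  if (is.null(calls)) calls <- cohort_calls(cohort, config)
  genomic <- has_genomic_data(cohort, subgroup_calls$case_id)
  wt <- subgroup_calls[genomic &
                         !(subgroup_calls$label %in% c("DMG", "IDH")), ,
                       drop = FALSE]
  cl <- cohort$clinical[match(wt$case_id, cohort$clinical$case_id), ]
  cluster <- assign_histologic_cluster(cl$histologic_pattern, histo_config)
  keep <- !is.na(cluster)
  ids <- wt$case_id[keep]; cluster <- cluster[keep]
  status <- vapply(ids, function(i)
    case_feature_status(cohort, i, calls[[i]], config)[features],
    logical(length(features)))
  if (length(features) == 1L) status <- matrix(status, nrow = 1,
                                               dimnames = list(features))
  out <- list()
  for (cl_name in GBM_HISTO_CLUSTERS) {
    in_cl <- cluster == cl_name
    if (!any(in_cl)) {
      out[[length(out) + 1]] <- data.frame(
        cluster = cl_name, feature = features, in_cluster_pos = NA_integer_,
        in_cluster_neg = NA_integer_, out_cluster_pos = NA_integer_,
        out_cluster_neg = NA_integer_, odds_ratio = NA_real_,
        p_value = NA_real_, note = "cluster absent from cohort",
        stringsAsFactors = FALSE)
      next
    }
    for (f in features) {
      s <- status[f, ]
      ok <- !is.na(s)
      tab <- table(factor(in_cl[ok], levels = c(TRUE, FALSE)),
                   factor(s[ok], levels = c(TRUE, FALSE)))
      ft <- stats::fisher.test(tab)
      out[[length(out) + 1]] <- data.frame(
        cluster = cl_name, feature = f,
        in_cluster_pos = tab[1, 1], in_cluster_neg = tab[1, 2],
        out_cluster_pos = tab[2, 1], out_cluster_neg = tab[2, 2],
        odds_ratio = unname(ft$estimate), p_value = ft$p.value, note = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
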