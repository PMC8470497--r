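## Deterministic per-gene call logic.

#' Gene amplification call
#'
#' Amplification is called for a gene-level copy number of 7 or more.
#'
#' @param copy_number non-negative copy number (vectorized).
#' @param threshold copy-number cutoff, default 7.
#' @return logical.
#' @export
call_amplification <- function(copy_number, threshold = 7) {
  stopifnot(all(copy_number >= 0, na.rm = TRUE))
  !is.na(copy_number) & copy_number >= threshold
}

#' Overexpression call
#'
#' A tumor/control fold-change of at least `threshold` (default 5) is called
#' overexpressed.
#'
#' @param fold positive fold-change (vectorized).
#' @param threshold fold cutoff, default 5.
#' @return logical.
#' @export
call_overexpression <- function(fold, threshold = 5) {
  stopifnot(all(fold > 0, na.rm = TRUE))
  fold >= threshold
}

#' Composite TERT activation call
#'
#' Telomerase activation by either TERT promoter mutation or, in the absence
#' of mutation, TERT overexpression. With no promoter mutation and no
#' expression data the composite is indeterminate and `NA` is returned.
#'
#' @param promoter_mutated logical.
#' @param tert_fold TERT fold-change or `NA` when expression is unavailable.
#' @param threshold overexpression cutoff, default 5.
#' @return logical (`NA` = unknown).
#' @export
call_tert_activation <- function(promoter_mutated, tert_fold = NA_real_,
                                 threshold = 5) {
  ifelse(promoter_mutated, TRUE,
         ifelse(is.na(tert_fold), NA, tert_fold >= threshold))
}

#' MGMT promoter methylation call
#'
#' Quantitative methylation values of 5 or more are positive.
#'
#' @param value non-negative methylation value, `NA` when not assayed.
#' @param threshold positivity cutoff, default 5.
#' @return character: "positive", "negative" or "unknown".
#' @export
call_mgmt_methylated <- function(value, threshold = 5) {
  if (any(value < 0, na.rm = TRUE)) stop("MGMT methylation value must be >= 0")
  ifelse(is.na(value), "unknown",
         ifelse(value >= threshold, "positive", "negative"))
}

## is a variant row a pathogenic/likely-pathogenic small variant?
is_pathogenic_small <- function(kind, pathogenicity) {
  kind %in% c("missense", "truncating", "frameshift", "splice_variant") &
    pathogenicity %in% c("pathogenic", "likely_pathogenic")
}

#' Biallelic inactivation call for a tumor suppressor
#'
#' True when a gene carries two hits: at least two distinct
#' pathogenic/likely-pathogenic small variants (pathogenic frameshift
#' fusions count as inactivating hits), or one such hit plus loss of
#' heterozygosity, or homozygous loss.
#'
#' @param events data.frame of events on one gene with columns `kind`,
#'   `pathogenicity` and optionally `loh` (logical).
#' @return logical scalar.
#' @export
call_biallelic <- function(events) {
  if (nrow(events) == 0L) return(FALSE)
  path <- c("pathogenic", "likely_pathogenic")
  hits <- sum(is_pathogenic_small(events$kind, events$pathogenicity)) +
    sum(events$kind == "fusion" & events$pathogenicity %in% path)
  loh <- any(events$kind == "loh") ||
    (!is.null(events$loh) && any(events$loh %in% TRUE))
  homoloss <- any(events$kind == "homozygous_loss")
  homoloss || hits >= 2 || (hits >= 1 && loh)
}

#' Per-gene alteration calls for one case
#'
#' Combines the variant, copy-number, fusion and expression payloads of a
#' case into one row per gene: amplification (CN >= 7), low CN gain
#' (2 < CN < 7), LOH, overexpression (`NA` when the case has no expression
#' data), fold-change, activating mutation, pathogenic in-frame fusion,
#' inactivating frameshift fusion, pathogenic small-variant count, promoter
#' mutation, homozygous and biallelic loss. Events flagged as belonging to a
#' secondary tumor focus are ignored.
#'
#' @param cohort a `gbm_cohort`.
#' @param id case id.
#' @param config a [classifier_config()].
#' @return data.frame, one row per gene with any event or with overexpression.
#' @export
gene_calls <- function(cohort, id, config = classifier_config()) {
  va <- cohort$variants[cohort$variants$case_id == id, , drop = FALSE]
  if (!is.null(va$secondary_focus))
    va <- va[!(va$secondary_focus %in% TRUE), , drop = FALSE]
  cn <- cohort$cn[cohort$cn$case_id == id, , drop = FALSE]
  fu <- cohort$fusions[cohort$fusions$case_id == id, , drop = FALSE]
  fold <- case_fold(cohort, id)
  has_expr <- !is.null(fold)

  over_genes <- if (has_expr)
    names(fold)[fold >= config$fold_threshold] else character()
  genes <- sort(unique(c(va$gene, cn$gene, fu$gene5, fu$gene3,
                         intersect(over_genes, config$rtk_genes))))
  if (!length(genes)) return(empty_gene_calls())

  path <- c("pathogenic", "likely_pathogenic")
  rows <- lapply(genes, function(g) {
    v <- va[va$gene == g, , drop = FALSE]
    cnr <- cn[cn$gene == g, , drop = FALSE]
    f5 <- fu[fu$gene5 == g | fu$gene3 == g, , drop = FALSE]
    cnv <- if (nrow(cnr)) max(cnr$copy_number) else NA_real_
    fg <- if (has_expr && g %in% names(fold)) unname(fold[g]) else NA_real_
    amplified <- (!is.na(cnv) && cnv >= config$cn_threshold) ||
      any(v$kind == "amplification")
    ev <- data.frame(kind = c(v$kind, rep("fusion", sum(f5$frame == "frameshift"))),
                     pathogenicity = c(v$pathogenicity,
                                       f5$pathogenicity[f5$frame == "frameshift"]),
                     loh = c(rep(FALSE, nrow(v)),
                             rep(FALSE, sum(f5$frame == "frameshift"))),
                     stringsAsFactors = FALSE)
    loh <- any(v$kind == "loh") || (nrow(cnr) && any(cnr$loh %in% TRUE))
    if (loh) ev <- rbind(ev, data.frame(kind = "loh", pathogenicity = "unknown",
                                        loh = TRUE))
    data.frame(
      gene = g,
      amplified = amplified,
      cn_gain = !is.na(cnv) && cnv > 2 && cnv < config$cn_threshold,
      copy_number = cnv,
      loh = loh,
      fold = fg,
      overexpressed = if (!has_expr || is.na(fg)) NA else
        fg >= config$fold_threshold,
      activating_mutation = any(v$activating %in% TRUE &
                                  v$pathogenicity %in% path),
      pathogenic_fusion = any(f5$pathogenicity %in% path &
                                f5$frame != "frameshift"),
      frameshift_fusion = any(f5$pathogenicity %in% path &
                                f5$frame == "frameshift"),
      n_pathogenic_small = sum(is_pathogenic_small(v$kind, v$pathogenicity)),
      promoter_mutation = any(v$kind == "promoter_mutation" &
                                v$pathogenicity %in% path),
      homozygous_loss = any(v$kind == "homozygous_loss") ||
        (!is.na(cnv) && cnv == 0),
      germline_pathogenic = any(v$germline %in% TRUE &
                                  v$pathogenicity %in% path),
      biallelic_loss = call_biallelic(ev),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_gene_calls <- function() {
  data.frame(gene = character(), amplified = logical(), cn_gain = logical(),
             copy_number = numeric(), loh = logical(), fold = numeric(),
             overexpressed = logical(), activating_mutation = logical(),
             pathogenic_fusion = logical(), frameshift_fusion = logical(),
             n_pathogenic_small = integer(), promoter_mutation = logical(),
             homozygous_loss = logical(), germline_pathogenic = logical(),
             biallelic_loss = logical(), stringsAsFactors = FALSE)
}

#' Per-gene calls for every case of a cohort
#' @param cohort a `gbm_cohort`.
#' @param config a [classifier_config()].
#' @return named list of [gene_calls()] data.frames, one per case.
#' @export
cohort_calls <- function(cohort, config = classifier_config()) {
  ids <- case_ids(cohort)
  stats::setNames(lapply(ids, function(i) gene_calls(cohort, i, config)), ids)
}
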