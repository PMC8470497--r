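## Correlation-based hierarchical clustering of the molecular subgroups.

#' Compound proliferation score of an expression profile
#'
#' Arithmetic mean fold-change over a set of proliferation marker genes
#' (default MKI67 alone; extendable, e.g. to PCNA or TOP2A).
#'
#' @param fold named fold-change vector of one case.
#' @param marker_genes marker gene set, default `"MKI67"`.
#' @return mean fold over the markers present, or `NA` if none is present.
#' @export
proliferation_score <- function(fold, marker_genes = "MKI67") {
  present <- intersect(marker_genes, names(fold))
  if (!length(present)) return(NA_real_)
  mean(fold[present])
}

#' Per-subgroup feature vectors for clustering
#'
#' One vector per subgroup: every frequency-matrix row (percent scale) plus
#' the subgroup mean CDK6 fold-change and mean proliferation score. Missing
#' expression means are imputed with the across-subgroup mean so the
#' feature ordering stays identical for all subgroups.
#'
#' @param summary a `cohort_summary` from [frequency_matrix()].
#' @param cohort the classified `gbm_cohort`.
#' @param subgroup_calls result of [classify_cohort()].
#' @param marker_genes proliferation markers, see [proliferation_score()].
#' @return numeric matrix, features x subgroups.
#' @export
subgroup_feature_vectors <- function(summary, cohort, subgroup_calls,
                                     marker_genes = "MKI67") {
  sc <- subgroup_calls[subgroup_calls$label != "DMG", , drop = FALSE]
  sc$col <- subgroup_column(sc$label)
  cols <- colnames(summary$matrix)
  cols <- cols[cols != "Total" & summary$n[cols] > 0]
  expr_mean <- function(gene_fun) {
    vapply(cols, function(g) {
      ids <- intersect(sc$case_id[sc$col == g],
                       colnames(cohort$fold %||% matrix(0, 0, 0)))
      if (!length(ids)) return(NA_real_)
      v <- vapply(ids, function(i) gene_fun(case_fold(cohort, i)), numeric(1))
      mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  cdk6 <- expr_mean(function(f) if ("CDK6" %in% names(f))
    unname(f["CDK6"]) else NA_real_)
  prolif <- expr_mean(function(f) proliferation_score(f, marker_genes))
  impute <- function(v) { v[is.nan(v) | is.na(v)] <- mean(v, na.rm = TRUE); v }
  rbind(summary$matrix[, cols, drop = FALSE],
        CDK6_fold = impute(cdk6), proliferation = impute(prolif))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation matrix of subgroup feature vectors
#'
#' Correlates the raw feature vectors by default: the percent-scale rows
#' dominate and carry the biological signal. `scale = TRUE` z-scores each
#' feature across subgroups first; this gives near-constant rows (rare
#' single-gene events) the same weight as the major pathway rows and is
#' offered as a sensitivity toggle.
#'
#' @param vectors features x subgroups matrix.
#' @param scale z-score features first, default FALSE.
#' @return symmetric correlation matrix (diagonal 1).
#' @export
correlation_matrix <- function(vectors, scale = FALSE) {
  if (ncol(vectors) < 2) stop("need at least 2 subgroup vectors")
  if (nrow(vectors) < 3) stop("need at least 3 features")
  sds <- apply(vectors, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature vector for subgroup: ",
         paste(colnames(vectors)[sds == 0], collapse = ", "))
  m <- if (scale) t(base::scale(t(vectors))) else vectors
  m <- m[apply(m, 1, function(r) all(is.finite(r))), , drop = FALSE]
  stats::cor(m, method = "pearson")
}

#' Hierarchical clustering of subgroups on correlation distance
#'
#' Agglomerative clustering on `d = 1 - r`. Ties are made deterministic by
#' ordering leaves lexicographically before clustering.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param linkage "average" (default), "complete" or "single".
#' @return an `hclust` object (heights on the 1 - r scale).
#' @export
cluster_subgroups <- function(corr, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  ord <- order(colnames(corr))
  d <- stats::as.dist(1 - corr[ord, ord])
  stats::hclust(d, method = linkage)
}

#' Leaf labels of each subtree at a k-group cut
#' @param hc an `hclust`.
#' @param k number of groups.
#' @return list of character vectors (sorted labels per group).
#' @export
cut_groups <- function(hc, k) {
  ct <- stats::cutree(hc, k = k)
  unname(lapply(split(names(ct), ct), sort))
}

#' Export a subgroup dendrogram in Newick format
#'
#' Branch lengths correspond to the merge heights of the clustering.
#'
#' @param hc an `hclust` from [cluster_subgroups()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
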