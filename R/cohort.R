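## Cohort container and tabular interchange readers/writers.
##
## A `gbm_cohort` bundles the five interchange tables plus the gene
## annotation and the derived per-case expression fold-changes:
##   clinical  - one row per case (demographics, IHC, histology, MGMT, survival)
##   variants  - gene-level small variants / promoter mutations (MAF-like)
##   cn        - gene-level copy number and LOH
##   fusions   - gene fusions (5'/3' partners, frame, pathogenicity)
##   expr      - raw counts, genes x samples; control columns prefixed "control:"
##   fold      - genes x tumor samples fold-change over the mean of controls,
##               computed after the count/pseudogene/chrY filters

CLINICAL_COLS <- c("case_id", "age", "sex", "ethnicity", "location",
                   "survival_months", "event_observed", "idh1_r132h",
                   "h3_k27m", "gfap", "p53", "ki67", "histologic_pattern",
                   "mgmt_value")
VARIANT_COLS <- c("case_id", "gene", "kind", "pathogenicity", "activating",
                  "germline", "hgvs")
CN_COLS <- c("case_id", "gene", "copy_number", "loh")
FUSION_COLS <- c("case_id", "gene5", "gene3", "frame", "pathogenicity")
ANNOTATION_COLS <- c("gene", "is_pseudogene", "chromosome")

#' Construct a cohort object from in-memory tables
#'
#' @param clinical data.frame with the clinical interchange columns.
#' @param variants,cn,fusions molecular tables (may have zero rows).
#' @param expr numeric matrix of raw counts, genes as rows; control sample
#'   columns are identified by a `control:` name prefix. May be `NULL`.
#' @param annotation gene annotation (gene, is_pseudogene, chromosome) used
#'   for the pseudogene/Y-chromosome expression filters. May be `NULL`.
#' @param name cohort name.
#' @param normalize_libsize divide each expression column by its total
#'   (counts per million) before fold-change computation. Default off.
#' @return object of class `gbm_cohort`.
#' @export
new_cohort <- function(clinical, variants = NULL, cn = NULL, fusions = NULL,
                       expr = NULL, annotation = NULL, name = "cohort",
                       normalize_libsize = FALSE) {
  variants <- empty_if_null(variants, VARIANT_COLS)
  cn <- empty_if_null(cn, CN_COLS)
  fusions <- empty_if_null(fusions, FUSION_COLS)
  validate_clinical(clinical)
  for (tab in list(variants = variants, cn = cn, fusions = fusions)) {
    bad <- setdiff(unique(tab$case_id), clinical$case_id)
    if (length(bad))
      stop("molecular table refers to unknown case_id: ",
           paste(bad, collapse = ", "))
  }
  fold <- NULL
  filtered <- character()
  if (!is.null(expr)) {
    expr <- as.matrix(expr)
    keep <- filter_expression_genes(expr, annotation)
    filtered <- setdiff(rownames(expr), keep)
    is_ctrl <- startsWith(colnames(expr), "control:")
    if (!any(is_ctrl)) stop("expression matrix has no 'control:' columns")
    bad <- setdiff(colnames(expr)[!is_ctrl], clinical$case_id)
    if (length(bad))
      stop("expression matrix refers to unknown case_id: ",
           paste(bad, collapse = ", "))
    mat <- expr[keep, , drop = FALSE]
    if (normalize_libsize) mat <- sweep(mat, 2, colSums(mat) / 1e6, "/")
    fold <- compute_fold_change(mat[, !is_ctrl, drop = FALSE],
                                mat[, is_ctrl, drop = FALSE])
  }
  structure(list(clinical = clinical, variants = variants, cn = cn,
                 fusions = fusions, expr = expr, annotation = annotation,
                 fold = fold, filtered_genes = filtered, name = name),
            class = "gbm_cohort")
}

empty_if_null <- function(x, cols) {
  if (is.null(x)) {
    x <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                       cols))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing))
    stop("table is missing columns: ", paste(missing, collapse = ", "))
  x
}

validate_clinical <- function(clinical) {
  missing <- setdiff(CLINICAL_COLS, names(clinical))
  if (length(missing))
    stop("clinical table is missing columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$case_id))
    stop("duplicate case_id in clinical table: ",
         clinical$case_id[duplicated(clinical$case_id)][1])
  if (nrow(clinical) == 0L) stop("clinical table is empty")
  check_enum(clinical$sex, GBM_SEX, "sex")
  check_enum(clinical$ethnicity, c(GBM_ETHNICITY, NA), "ethnicity")
  check_enum(clinical$location, GBM_LOCATION, "location")
  check_enum(clinical$idh1_r132h, GBM_IHC_3, "idh1_r132h")
  check_enum(clinical$h3_k27m, GBM_IHC_3, "h3_k27m")
  check_enum(clinical$gfap, GBM_GFAP, "gfap")
  check_enum(clinical$histologic_pattern, c(GBM_PATTERNS, "unknown"),
             "histologic_pattern")
  if (any(clinical$age <= 0)) stop("age must be positive")
  if (any(clinical$survival_months < 0)) stop("survival_months must be >= 0")
  invisible(clinical)
}

check_enum <- function(x, allowed, what) {
  bad <- which(!(x %in% allowed | is.na(x)))
  if (length(bad))
    stop(sprintf("malformed %s value '%s' in row %d", what, x[bad[1]], bad[1]))
}

## Genes passing the expression filters: raw count >= 500 in at least one
## tumor sample; pseudogenes and Y-chromosome genes excluded.
filter_expression_genes <- function(expr, annotation) {
  is_ctrl <- startsWith(colnames(expr), "control:")
  tumor <- expr[, !is_ctrl, drop = FALSE]
  keep <- if (ncol(tumor)) {
    rownames(expr)[apply(tumor, 1, max) >= 500]
  } else rownames(expr)
  if (!is.null(annotation)) {
    drop <- annotation$gene[annotation$is_pseudogene |
                              annotation$chromosome %in% c("Y", "chrY")]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Per-gene expression fold-change over the mean of control samples
#'
#' For each gene, the tumor value divided by the arithmetic mean of the
#' low-grade glioma control samples. Genes with a zero control mean cannot
#' be expressed as a ratio: they are returned as `NA` and listed in the
#' `zero_control` attribute so downstream thresholding skips them.
#'
#' @param tumor_counts named numeric vector or genes x samples matrix.
#' @param control_counts genes x samples matrix (or vector) of control counts.
#' @return same shape as `tumor_counts`, positive fold-changes with a
#'   `zero_control` attribute.
#' @export
compute_fold_change <- function(tumor_counts, control_counts) {
  cc <- as.matrix(control_counts)
  if (ncol(cc) == 0L || nrow(cc) == 0L) stop("control table is empty")
  if (any(cc < 0, na.rm = TRUE)) stop("counts must be non-negative")
  ctrl_mean <- rowMeans(cc)
  vec_in <- is.null(dim(tumor_counts))
  tm <- if (vec_in) matrix(tumor_counts, ncol = 1,
                           dimnames = list(names(tumor_counts), "tumor"))
        else as.matrix(tumor_counts)
  shared <- intersect(rownames(tm), names(ctrl_mean))
  if (!length(shared)) stop("no genes shared between tumor and control tables")
  tm <- tm[shared, , drop = FALSE]
  fold <- sweep(tm, 1, ctrl_mean[shared], "/")
  zero <- shared[ctrl_mean[shared] == 0]
  fold[zero, ] <- NA_real_
  out <- if (vec_in) stats::setNames(fold[, 1], rownames(fold)) else fold
  attr(out, "zero_control") <- zero
  out
}

#' Read a cohort from its interchange files
#'
#' @param clinical_table CSV path; `variant_table`, `cn_table`,
#'   `fusion_table`, `expression_matrix`, `gene_annotation` TSV paths
#'   (molecular tables optional).
#' @param name cohort name.
#' @param normalize_libsize see [new_cohort()].
#' @return a `gbm_cohort`.
#' @export
read_cohort <- function(clinical_table, variant_table = NULL, cn_table = NULL,
                        fusion_table = NULL, expression_matrix = NULL,
                        gene_annotation = NULL, name = "cohort",
                        normalize_libsize = FALSE) {
  clinical <- utils::read.csv(clinical_table, stringsAsFactors = FALSE)
  clinical$event_observed <- as.logical(clinical$event_observed)
  read_tsv <- function(p) if (is.null(p)) NULL else
    utils::read.delim(p, stringsAsFactors = FALSE)
  variants <- read_tsv(variant_table)
  if (!is.null(variants)) {
    variants$activating <- as.logical(variants$activating)
    variants$germline <- as.logical(variants$germline)
    if (!"secondary_focus" %in% names(variants))
      variants$secondary_focus <- FALSE
    variants$secondary_focus <- as.logical(variants$secondary_focus)
  }
  cn <- read_tsv(cn_table)
  if (!is.null(cn)) cn$loh <- as.logical(cn$loh)
  fusions <- read_tsv(fusion_table)
  expr <- NULL
  if (!is.null(expression_matrix)) {
    expr <- as.matrix(utils::read.delim(expression_matrix, row.names = 1,
                                        check.names = FALSE))
  }
  annotation <- read_tsv(gene_annotation)
  if (!is.null(annotation))
    annotation$is_pseudogene <- as.logical(annotation$is_pseudogene)
  new_cohort(clinical, variants, cn, fusions, expr, annotation, name = name,
             normalize_libsize = normalize_libsize)
}

#' Write a cohort to a directory of interchange files
#'
#' Emits clinical.csv, variants.tsv, cn.tsv, fusions.tsv, expression.tsv,
#' annotation.tsv and, when the cohort carries generator truth labels,
#' truth.tsv (never read back by the classifier).
#'
#' @param cohort a `gbm_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wt(cohort$variants, "variants.tsv")
  wt(cohort$cn, "cn.tsv")
  wt(cohort$fusions, "fusions.tsv")
  if (!is.null(cohort$expr)) {
    df <- data.frame(gene = rownames(cohort$expr), cohort$expr,
                     check.names = FALSE)
    wt(df, "expression.tsv")
  }
  if (!is.null(cohort$annotation)) wt(cohort$annotation, "annotation.tsv")
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) wt(truth, "truth.tsv")
  invisible(dir)
}

#' Read a cohort previously written with [write_cohort()]
#' @param dir directory produced by [write_cohort()].
#' @param name cohort name.
#' @return a `gbm_cohort`.
#' @export
read_cohort_dir <- function(dir, name = basename(dir)) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (file.exists(fp)) fp else NULL
  }
  read_cohort(file.path(dir, "clinical.csv"), p("variants.tsv"), p("cn.tsv"),
              p("fusions.tsv"), p("expression.tsv"), p("annotation.tsv"),
              name = name)
}

#' @export
print.gbm_cohort <- function(x, ...) {
  n_expr <- if (is.null(x$fold)) 0L else ncol(x$fold)
  cat(sprintf("<gbm_cohort '%s'> %d cases (%d with expression)\n", x$name,
              nrow(x$clinical), n_expr))
  cat(sprintf("  variants: %d  cn: %d  fusions: %d\n", nrow(x$variants),
              nrow(x$cn), nrow(x$fusions)))
  invisible(x)
}

#' Case ids of a cohort
#' @param cohort a `gbm_cohort`.
#' @return character vector.
#' @export
case_ids <- function(cohort) cohort$clinical$case_id

#' Does a case have any sequencing (genomic) data?
#' @param cohort a `gbm_cohort`.
#' @param id case id (vectorized).
#' @return logical vector.
#' @export
has_genomic_data <- function(cohort, id = case_ids(cohort)) {
  id %in% c(cohort$variants$case_id, cohort$cn$case_id,
            cohort$fusions$case_id)
}

## Expression fold-change profile of one case (NULL if no expression data)
case_fold <- function(cohort, id) {
  if (is.null(cohort$fold) || !(id %in% colnames(cohort$fold))) return(NULL)
  f <- stats::setNames(cohort$fold[, id], rownames(cohort$fold))
  f[!is.na(f)]
}
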