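## Per-case pathology-style report and the command-line entry points.

GLIOCLASS_REPORT_SCHEMA <- "glioclass-report/1"

#' Per-case molecular pathology report
#'
#' Bundles the subgroup call with its driver evidence chain, histologic
#' pattern and cluster, composite pathway statuses, MGMT call, the
#' classifier configuration hash and the tool version into one serializable
#' record (JSON is the canonical rendering).
#'
#' @param cohort a `gbm_cohort`.
#' @param id case id.
#' @param config a [classifier_config()].
#' @param histo_config a [histology_config()].
#' @return list of class `case_report`.
#' @export
case_report <- function(cohort, id, config = classifier_config(),
                        histo_config = histology_config()) {
  calls <- gene_calls(cohort, id, config)
  sc <- classify_case(cohort, id, config, calls = calls)
  ps <- pathway_status(cohort, id, calls, config)
  cl <- cohort$clinical[cohort$clinical$case_id == id, , drop = FALSE]
  structure(list(
    schema = GLIOCLASS_REPORT_SCHEMA,
    case_id = id,
    subgroup = list(label = sc$label,
                    drivers = as.list(sc$drivers),
                    rules = sc$rationale,
                    flags = sc$flags),
    histology = list(pattern = cl$histologic_pattern,
                     cluster = assign_histologic_cluster(
                       cl$histologic_pattern, histo_config)),
    pathways = unclass(ps)[c("tert_path", "pi3k_mtor", "g1_phase",
                             "tp53_path", "ddr_path", "mmr", "swi_snf",
                             "other_chrm")],
    mgmt = ps$mgmt,
    config_hash = config$hash,
    tool_version = as.character(utils::packageVersion("glioclass"))),
    class = "case_report")
}

#' Serialize a case report as JSON
#' @param report a [case_report()].
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("== %s ==\nMolecular subgroup: %s\n", x$case_id,
              x$subgroup$label))
  if (length(x$subgroup$drivers))
    cat("Drivers:", paste(names(x$subgroup$drivers),
                          unlist(x$subgroup$drivers), sep = ":",
                          collapse = "; "), "\n")
  cat(sprintf("Histology: %s (cluster %s)\n", x$histology$pattern,
              x$histology$cluster))
  on <- names(which(vapply(x$pathways, isTRUE, logical(1))))
  cat("Pathways altered:", if (length(on)) paste(on, collapse = ", ")
      else "none", "\n")
  cat(sprintf("MGMT promoter methylation: %s\n", x$mgmt))
  cat(sprintf("[config %s, glioclass %s]\n", substr(x$config_hash, 1, 8),
              x$tool_version))
  invisible(x)
}

cli_usage <- function() {
  cat("usage: glioclass <command> [options]\n",
      "commands:\n",
      "  simulate  --seed <int> --out <dir>\n",
      "  classify  <cohort-dir> --out <tsv>\n",
      "  summarize <cohort-dir> --out <tsv>\n",
      "  cluster   <cohort-dir> --out <newick>\n",
      "  survive   <cohort-dir> --out <tsv>\n",
      "  report    <cohort-dir> --case <id> [--out <json>]\n", sep = "")
}

cli_opt <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag)
  args[i[1] + 1]
}

#' Command-line entry point
#'
#' Thin shell over the package functions: `simulate` writes a synthetic
#' cohort, `classify` emits per-case subgroup calls, `summarize` the
#' frequency matrix, `cluster` the subgroup dendrogram (Newick), `survive`
#' per-subgroup Kaplan-Meier medians, and `report` a per-case JSON report.
#'
#' @param args character vector of command-line arguments.
#' @return exit code (0 ok, 2 usage error), invisibly.
#' @export
glioclass_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(2L)) }
  cmd <- args[1]; rest <- args[-1]
  ok <- tryCatch({
    switch(cmd,
      simulate = {
        seed <- as.integer(cli_opt(rest, "--seed", "1"))
        out <- cli_opt(rest, "--out")
        if (is.null(out)) stop("simulate needs --out")
        co <- generate_cohort(generator_config(seed = seed))
        write_cohort(co, out)
        message("wrote ", nrow(co$clinical), " cases to ", out)
      },
      classify = {
        co <- read_cohort_dir(rest[1])
        out <- cli_opt(rest, "--out")
        sc <- classify_cohort(co, verbose = TRUE)
        if (is.null(out)) print(sc)
        else utils::write.table(sc, out, sep = "\t", row.names = FALSE,
                                quote = FALSE)
      },
      summarize = {
        co <- read_cohort_dir(rest[1])
        out <- cli_opt(rest, "--out")
        if (is.null(out)) stop("summarize needs --out")
        fm <- frequency_matrix(co, classify_cohort(co))
        write_frequency_matrix(fm, out)
      },
      cluster = {
        co <- read_cohort_dir(rest[1])
        out <- cli_opt(rest, "--out")
        if (is.null(out)) stop("cluster needs --out")
        sc <- classify_cohort(co)
        fm <- frequency_matrix(co, sc)
        hc <- cluster_subgroups(correlation_matrix(
          subgroup_feature_vectors(fm, co, sc)))
        write_dendrogram_newick(hc, out)
      },
      survive = {
        co <- read_cohort_dir(rest[1])
        out <- cli_opt(rest, "--out")
        sc <- classify_cohort(co)
        cl <- merge(co$clinical, sc[, c("case_id", "label")], by = "case_id")
        med <- vapply(split(cl, cl$label), function(x)
          km_median(km_fit(x$survival_months, x$event_observed)), numeric(1))
        df <- data.frame(subgroup = names(med), median_months = med)
        if (is.null(out)) print(df)
        else utils::write.table(df, out, sep = "\t", row.names = FALSE,
                                quote = FALSE)
      },
      report = {
        co <- read_cohort_dir(rest[1])
        id <- cli_opt(rest, "--case")
        if (is.null(id)) stop("report needs --case")
        rp <- case_report(co, id)
        out <- cli_opt(rest, "--out")
        if (is.null(out)) cat(report_json(rp), "\n") else report_json(rp, out)
      },
      { cli_usage(); return(invisible(2L)) })
    TRUE
  }, error = function(e) { message("error: ", conditionMessage(e)); FALSE })
  invisible(if (ok) 0L else 1L)
}
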