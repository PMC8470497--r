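## Shared fixtures: the deterministic cohort (built once per test run) and
## a builder for tiny hand-made cohorts.

.glioclass_test_env <- new.env(parent = emptyenv())

fixture_bundle <- function() {
  if (is.null(.glioclass_test_env$bundle)) {
    co <- deterministic_fixture()
    calls <- cohort_calls(co)
    sc <- suppressWarnings(classify_cohort(co, calls = calls))
    .glioclass_test_env$bundle <- list(
      co = co, calls = calls, sc = sc,
      fm = frequency_matrix(co, sc, calls = calls))
  }
  .glioclass_test_env$bundle
}

blank_clinical <- function(ids, idh1 = "negative", h3 = "negative",
                           pattern = "unknown", mgmt = NA_real_,
                           survival = 10, event = TRUE) {
  n <- length(ids)
  data.frame(case_id = ids, age = 60L, sex = rep(c("M", "F"), length.out = n),
             ethnicity = "White", location = "frontal",
             survival_months = rep(survival, length.out = n),
             event_observed = rep(event, length.out = n),
             idh1_r132h = rep(idh1, length.out = n),
             h3_k27m = rep(h3, length.out = n), gfap = "high",
             p53 = 1L, ki67 = 20,
             histologic_pattern = rep(pattern, length.out = n),
             mgmt_value = rep(mgmt, length.out = n),
             stringsAsFactors = FALSE)
}

variant_row <- function(id, gene, kind = "missense", path = "pathogenic",
                        activating = FALSE, germline = FALSE) {
  data.frame(case_id = id, gene = gene, kind = kind, pathogenicity = path,
             activating = activating, germline = germline, hgvs = ".",
             secondary_focus = FALSE, stringsAsFactors = FALSE)
}

cn_row <- function(id, gene, copy_number, loh = FALSE) {
  data.frame(case_id = id, gene = gene, copy_number = copy_number, loh = loh,
             stringsAsFactors = FALSE)
}

fusion_row <- function(id, g5, g3, frame = "in_frame", path = "pathogenic") {
  data.frame(case_id = id, gene5 = g5, gene3 = g3, frame = frame,
             pathogenicity = path, stringsAsFactors = FALSE)
}

## single- or few-case cohort; `fold` is a list case_id -> named fold vector
mini_cohort <- function(ids = "C1", variants = NULL, cn = NULL,
                        fusions = NULL, fold = NULL, clinical = NULL) {
  if (is.null(clinical)) clinical <- blank_clinical(ids)
  expr <- NULL
  if (!is.null(fold)) {
    genes <- unique(unlist(lapply(fold, names)))
    expr <- matrix(1000, length(genes), length(fold) + 1,
                   dimnames = list(genes, c(names(fold), "control:LGG1")))
    for (s in names(fold)) {
      expr[, s] <- 1000
      expr[names(fold[[s]]), s] <- fold[[s]] * 1000
    }
  }
  new_cohort(clinical, variants, cn, fusions, expr, annotation = NULL,
             name = "mini")
}
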