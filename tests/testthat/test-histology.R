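test_that("pattern-to-cluster mapping is total, deterministic and overridable", {
  cfg <- histology_config()
  expect_setequal(names(cfg$pattern_to_cluster), GBM_PATTERNS)
  expect_true(all(cfg$pattern_to_cluster %in% GBM_HISTO_CLUSTERS))
  expect_equal(assign_histologic_cluster("fibroblastic"), "Spindle")
  expect_equal(assign_histologic_cluster("hgne"), "Anaplastic")
  expect_equal(assign_histologic_cluster("epithelioid"), "Epithelioid")
  expect_equal(assign_histologic_cluster("egfr"), "EGFR_like")
  expect_equal(assign_histologic_cluster("pre_hgne"), "Small_neuronal")
  expect_true(is.na(assign_histologic_cluster("unknown")))
  expect_error(assign_histologic_cluster("spindloid"), "unknown histologic pattern")
  ## overriding one inferred pattern moves only that pattern
  cfg2 <- histology_config(overrides = c(pleomorphic = "Epithelioid"))
  expect_equal(assign_histologic_cluster("pleomorphic", cfg2), "Epithelioid")
  others <- setdiff(GBM_PATTERNS, "pleomorphic")
  expect_equal(assign_histologic_cluster(others, cfg2),
               assign_histologic_cluster(others, cfg))
  expect_error(histology_config(overrides = c(egfr = "Blobby")),
               "malformed histologic cluster")
})

test_that("planted histologic-molecular associations are detected", {
  b <- fixture_bundle()
  ha <- histo_molecular_association(b$co, b$sc, calls = b$calls)
  row <- ha[ha$cluster == "EGFR_like" & ha$feature == "CDKN2A_loss", ]
  expect_lt(row$p_value, 0.05)
  expect_gt(row$odds_ratio, 1)
  ## every EGFR-like case carries the CDKN2A/2B homozygous loss
  expect_equal(row$in_cluster_neg, 0L)
  ## epithelioid cluster: 70% TP53-mutant, 40% RB1-mutant
  ep <- ha[ha$cluster == "Epithelioid", ]
  tp53 <- ep[ep$feature == "TP53", ]
  expect_equal(tp53$in_cluster_pos /
                 (tp53$in_cluster_pos + tp53$in_cluster_neg), 0.7)
  rb1 <- ep[ep$feature == "RB1", ]
  expect_equal(rb1$in_cluster_pos /
                 (rb1$in_cluster_pos + rb1$in_cluster_neg), 0.4)
})

test_that("absent clusters are skipped with a note", {
  co <- mini_cohort(clinical = blank_clinical(c("A", "B"),
                                              pattern = c("egfr", "hgne")),
                    variants = rbind(variant_row("A", "PTEN", "truncating"),
                                     variant_row("B", "TP53")))
  ha <- histo_molecular_association(co, suppressWarnings(classify_cohort(co)),
                                    features = "TP53")
  sp <- ha[ha$cluster == "Spindle", ]
  expect_true(all(sp$note == "cluster absent from cohort"))
  expect_true(all(is.na(sp$p_value)))
})

test_that("shuffled histology labels give null-calibrated Fisher p-values", {
  b <- fixture_bundle()
  ps <- vapply(1:40, function(s) {
    set.seed(7000 + s)
    co <- b$co
    co$clinical$histologic_pattern <-
      sample(co$clinical$histologic_pattern)
    ha <- histo_molecular_association(co, b$sc, features = "CDKN2A_loss",
                                      calls = b$calls)
    ha$p_value[ha$cluster == "EGFR_like"]
  }, numeric(1))
  ## Fisher's exact p is conservative; demand no excess of false positives
  ## and a broadly spread distribution
  expect_lte(mean(ps < 0.05), 0.125)
  expect_gt(mean(ps), 0.3)
  expect_gt(stats::sd(ps), 0.1)
})
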