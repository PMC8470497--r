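test_that("pathway_status follows the composite gene-set definitions", {
  co <- mini_cohort("A", variants = variant_row("A", "PTEN", "truncating"))
  ps <- pathway_status(co, "A")
  expect_true(ps$pi3k_mtor)
  expect_false(ps$g1_phase); expect_false(ps$tp53_path)
  expect_false(ps$ddr_path); expect_false(ps$swi_snf)

  co <- mini_cohort("A", variants = variant_row("A", "TSC2", "truncating"))
  expect_true(pathway_status(co, "A")$pi3k_mtor)

  co <- mini_cohort("A", variants = variant_row("A", "MSH6", "truncating"))
  ps <- pathway_status(co, "A")
  expect_true(ps$mmr); expect_true(ps$ddr_path)

  co <- mini_cohort("A", variants = variant_row("A", "STAG2", "missense",
                                                path = "vus"))
  ps <- pathway_status(co, "A")   # VUS do not count; genomic data present
  expect_false(any(unlist(ps[c("pi3k_mtor", "g1_phase", "tp53_path",
                               "ddr_path", "mmr", "swi_snf",
                               "other_chrm")])))
  expect_equal(ps$mgmt, "unknown")
})

test_that("the fixture frequency matrix reproduces the reference profile cell by cell", {
  b <- fixture_bundle()
  ref <- gbm_reference_frequencies()
  got <- round(b$fm$matrix[rownames(ref), colnames(ref)], 1)
  expect_equal(got, round(ref, 1), tolerance = 1e-8)
  ## spot value: CDK4 amplification in the Other subgroup
  expect_equal(round(b$fm$matrix["CDK4_amp", "Other"], 1), 46.2)
  ## denominators reflect the partial TERT / MGMT assay coverage
  expect_equal(unname(b$fm$denominators["TERT", "EGFR_amp"]), 28)
  expect_equal(unname(b$fm$denominators["MGMT_methyl", "EGFR_amp"]), 30)
  expect_equal(unname(b$fm$denominators["PTEN", "EGFR_amp"]), 33)
})

test_that("whole-cohort totals match the reference where it is self-consistent", {
  b <- fixture_bundle()
  tot <- gbm_reference_totals()
  for (i in seq_len(nrow(tot))) {
    got <- round(b$fm$matrix[tot$feature[i], "Total"], tot$digits[i])
    if (tot$consistent[i]) {
      expect_equal(got, tot$total[i],
                   info = paste("total for", tot$feature[i]))
    } else {
      ## the two internally inconsistent printed totals: the data-derived
      ## value is the sum of the per-subgroup cells
      expect_equal(got, c(PIK3CA = 16.1, STAG2 = 11.5)[[tot$feature[i]]])
    }
  }
})

test_that("composite frequencies dominate their member frequencies", {
  comp <- list(PI3K_mTOR = c("PTEN", "PIK3CA", "PIK3R1"),
               TP53_path = c("TP53", "MDM2_amp", "MDM4_amp", "RPL5", "PPM1D"),
               DDR_path = c("ATM", "BRCA2", "MMR"),
               G1_phase = c("CDKN2A_loss", "CDK4_amp", "RB1"))
  check <- function(fm) {
    for (cname in names(comp)) {
      mx <- apply(fm$matrix[comp[[cname]], , drop = FALSE], 2, max)
      ok <- is.na(mx) | fm$matrix[cname, ] >= mx - 1e-9
      expect_true(all(ok), info = cname)
    }
  }
  check(fixture_bundle()$fm)
  co <- generate_cohort(generator_config(seed = 42))
  check(frequency_matrix(co, classify_cohort(co)))
})

test_that("G1-phase events are mutually exclusive except two germline RB1 points", {
  b <- fixture_bundle()
  bad <- audit_g1_exclusivity(b$co, b$calls)
  expect_length(bad, 2)
  v <- b$co$variants
  for (id in bad) {
    rb1 <- v[v$case_id == id & v$gene == "RB1", ]
    expect_true(all(rb1$germline))
    expect_true(all(rb1$kind == "missense"))
  }
})

test_that("empty subgroups give missing rows and event-free cases give zeros", {
  co <- mini_cohort("A", variants = variant_row("A", "STAG2", "missense",
                                                path = "vus"))
  fm <- frequency_matrix(co, classify_cohort(co))
  expect_true(all(is.na(fm$matrix[, "EGFR_amp"])))  # subgroup absent
  mut_rows <- setdiff(rownames(fm$matrix), c("TERT", "MGMT_methyl"))
  expect_true(all(fm$matrix[mut_rows, "Other"] == 0))
  ## TSV export round-trips the layout
  p <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_matrix(fm, p)
  df <- read.delim(p)
  expect_equal(df$feature, rownames(fm$matrix))
})
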