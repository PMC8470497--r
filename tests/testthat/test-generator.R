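test_that("generation is byte-identical under a fixed seed", {
  a <- generate_cohort(generator_config(seed = 7))
  b <- generate_cohort(generator_config(seed = 7))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$variants, b$variants)
  expect_identical(a$cn, b$cn)
  expect_identical(a$fusions, b$fusions)
  expect_identical(a$expr, b$expr)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  d <- generate_cohort(generator_config(seed = 8))
  expect_false(identical(a$variants, d$variants))
})

test_that("a single-subgroup cohort is fully recoverable", {
  sizes <- c(NF1 = 10L)
  co <- generate_cohort(generator_config(seed = 3, subgroup_sizes = sizes))
  sc <- classify_cohort(co)
  expect_equal(nrow(sc), 10L)
  expect_true(all(sc$label == "G3_NF1"))
})

test_that("hidden labels are recovered exactly across seeds", {
  for (s in 1:10) {
    co <- generate_cohort(generator_config(seed = 200 + s))
    sc <- classify_cohort(co)
    m <- merge(sc, attr(co, "truth"), by = "case_id")
    expect_true(all(m$label == m$intended_label),
                info = paste("seed", 200 + s))
  }
})

test_that("seed-averaged frequency-matrix cells track the configured profile", {
  ref <- gbm_reference_frequencies()
  acc <- array(NA_real_, dim = c(nrow(ref), ncol(ref), 12))
  for (s in 1:12) {
    co <- generate_cohort(generator_config(seed = 400 + s))
    fm <- frequency_matrix(co, classify_cohort(co))
    acc[, , s] <- fm$matrix[rownames(ref), colnames(ref)]
  }
  dev <- abs(apply(acc, c(1, 2), mean, na.rm = TRUE) - ref)
  expect_lt(max(dev), 5)
})

test_that("infeasible frequency configurations fail before sampling", {
  f <- gbm_reference_frequencies()
  f["CDKN2A_loss", "Other"] <- 60
  f["CDK4_amp", "Other"] <- 30
  f["RB1", "Other"] <- 30   # exclusive events summing to 120%
  expect_error(generator_config(frequencies = f), "infeasible")
  f <- gbm_reference_frequencies()
  f["PI3K_mTOR", "FGFR3"] <- 10   # composite below its PTEN member
  expect_error(generator_config(frequencies = f), "infeasible")
})

test_that("the deterministic fixture carries the reference count structure", {
  b <- fixture_bundle()
  genomic <- has_genomic_data(b$co, b$sc$case_id)
  wt <- b$sc[genomic & !(b$sc$label %in% c("DMG", "IDH")), ]
  expect_equal(nrow(wt), 87L)
  ## six of the thirteen Other-subgroup cases are CDK4-amplified
  expect_equal(unname(b$fm$counts["CDK4_amp", "Other"]), 6)
  ## and ten IDH-wild-type cases in total
  expect_equal(unname(b$fm$counts["CDK4_amp", "Total"]), 10)
  ## all 33 EGFR-amplified drivers present
  ea <- wt$case_id[wt$label == "G1_EGFR_amp"]
  amp <- vapply(ea, function(i) {
    g <- b$calls[[i]]; any(g$gene == "EGFR" & g$amplified)
  }, logical(1))
  expect_equal(sum(amp), 33L)
})

test_that("planted survival parameters shape the generated survival data", {
  co <- generate_cohort(generator_config(seed = 77))
  cl <- merge(co$clinical, attr(co, "truth"), by = "case_id")
  ## censoring close to the configured 10%
  expect_lt(abs(mean(!cl$event_observed) - 0.1), 0.08)
  ## pooled large-sample median recovery for one subgroup
  d <- simulate_survival(500, gbm_survival_medians()[["FGFR3"]],
                         seed = 123)
  est <- km_median(km_fit(d$time, d$event))
  expect_gte(est, 18); expect_lte(est, 22)
})
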