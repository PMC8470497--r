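test_that("single-driver rule examples classify per the rule set", {
  ## EGFR amplified + overexpressed + vIII -> EGFR-amplified subgroup
  co <- mini_cohort("A",
                    variants = variant_row("A", "EGFR", "splice_variant",
                                           activating = TRUE),
                    cn = cn_row("A", "EGFR", 20),
                    fold = list(A = c(EGFR = 26)))
  expect_equal(classify_case(co, "A")$label, "G1_EGFR_amp")
  ## EGFR activating mutation without amplification -> EGFR-mutant-only
  co <- mini_cohort("A", variants = variant_row("A", "EGFR",
                                                activating = TRUE))
  expect_equal(classify_case(co, "A")$label, "G1_EGFR_mut")
  ## FGFR3 fusion -> FGFR3
  co <- mini_cohort("A", fusions = fusion_row("A", "FGFR3", "TACC3"))
  expect_equal(classify_case(co, "A")$label, "G2_FGFR3")
  ## NF1 truncating + LOH, no RTK driver -> NF1
  co <- mini_cohort("A", variants = variant_row("A", "NF1", "truncating"),
                    cn = cn_row("A", "NF1", 1, loh = TRUE))
  sc <- classify_case(co, "A")
  expect_equal(sc$label, "G3_NF1")
  expect_equal(unname(sc$drivers["NF1"]), "biallelic_inactivation")
  ## BRAF p.V600E -> RAF
  co <- mini_cohort("A", variants = variant_row("A", "BRAF",
                                                activating = TRUE))
  expect_equal(classify_case(co, "A")$label, "G4_RAF")
  ## PTEN mutation + TERT promoter only -> Other
  co <- mini_cohort("A", variants = rbind(
    variant_row("A", "PTEN", "truncating"),
    variant_row("A", "TERT", "promoter_mutation")))
  expect_equal(classify_case(co, "A")$label, "G7_Other")
})

test_that("Multi-RTK routing: multiple drivers, silent PDGFRA amplification, non-canonical RTKs", {
  ## PDGFRA amplified without overexpression plus high-fold MET
  co <- mini_cohort("A", cn = rbind(cn_row("A", "PDGFRA", 10),
                                    cn_row("A", "MET", 4)),
                    fold = list(A = c(PDGFRA = 1.2, MET = 40)))
  sc <- classify_case(co, "A")
  expect_equal(sc$label, "G6_MultiRTK")
  ## silent PDGFRA amplification alone is Multi-RTK
  co <- mini_cohort("A", cn = cn_row("A", "PDGFRA", 10),
                    fold = list(A = c(PDGFRA = 1.5)))
  expect_equal(classify_case(co, "A")$label, "G6_MultiRTK")
  ## but an activating mutation keeps an amplified low-fold case in G5
  co <- mini_cohort("A",
                    variants = variant_row("A", "PDGFRA", activating = TRUE),
                    cn = cn_row("A", "PDGFRA", 10),
                    fold = list(A = c(PDGFRA = 4.9)))
  expect_equal(classify_case(co, "A")$label, "G5_PDGFRA")
  ## a lone non-canonical RTK driver routes to Multi-RTK
  co <- mini_cohort("A", fusions = fusion_row("A", "LMNA", "NTRK1"))
  expect_equal(classify_case(co, "A")$label, "G6_MultiRTK")
  ## PDGFRA/KIT/KDR co-amplification counts as one locus driver
  co <- mini_cohort("A", cn = rbind(cn_row("A", "PDGFRA", 12),
                                    cn_row("A", "KIT", 9),
                                    cn_row("A", "KDR", 9)),
                    fold = list(A = c(PDGFRA = 16, KIT = 8, KDR = 10)))
  expect_equal(classify_case(co, "A")$label, "G5_PDGFRA")
})

test_that("IHC triage precedes genomic rules and contradictions error", {
  co <- mini_cohort(clinical = blank_clinical("A", h3 = "positive"),
                    cn = cn_row("A", "EGFR", 30))
  expect_equal(classify_case(co, "A")$label, "DMG")
  co <- mini_cohort(clinical = blank_clinical("A", idh1 = "positive"))
  expect_equal(classify_case(co, "A")$label, "IDH")
  co <- mini_cohort("A", variants = variant_row("A", "IDH1"))
  expect_equal(classify_case(co, "A")$label, "IDH")
  co <- mini_cohort(clinical = blank_clinical("A", idh1 = "positive",
                                              h3 = "positive"))
  expect_error(classify_case(co, "A"), "contradictory IHC")
})

test_that("a case with no molecular data and negative IHC is Other with a warning flag", {
  co <- mini_cohort("A")
  expect_warning(sc <- classify_case(co, "A"), "no molecular data")
  expect_equal(sc$label, "G7_Other")
  expect_true("no_molecular_data" %in% sc$flags)
})

test_that("classification partitions the fixture into the reference subgroup sizes", {
  b <- fixture_bundle()
  expect_equal(nrow(b$sc), nrow(b$co$clinical))   # exactly one label per case
  expect_false(any(is.na(b$sc$label)))
  cnt <- table(b$sc$label)
  expect_equal(as.integer(cnt[c("G1_EGFR_amp", "G1_EGFR_mut", "G5_PDGFRA",
                                "G6_MultiRTK", "G2_FGFR3", "G3_NF1",
                                "G4_RAF")]),
               c(33L, 3L, 7L, 7L, 5L, 15L, 4L))
  expect_equal(as.integer(cnt["G7_Other"]), 16L)  # 13 + 3 IHC-only cases
  expect_equal(as.integer(cnt["DMG"]), 3L)
  expect_equal(as.integer(cnt["IDH"]), 8L)
  expect_equal(sum(cnt), 101L)
})

test_that("removing a non-driver VUS never changes a label", {
  b <- fixture_bundle()
  vus <- which(b$co$variants$pathogenicity == "vus")
  expect_gt(length(vus), 0)
  for (i in vus) {
    co2 <- b$co
    id <- co2$variants$case_id[i]
    co2$variants <- co2$variants[-i, ]
    expect_equal(classify_case(co2, id)$label,
                 b$sc$label[b$sc$case_id == id])
  }
})

test_that("no case satisfies two single-driver subgroup definitions", {
  b <- fixture_bundle()
  expect_false(any(grepl("conflict", b$sc$flags)))
  for (s in 1:8) {
    co <- generate_cohort(generator_config(seed = 100 + s))
    sc <- classify_cohort(co)
    expect_false(any(grepl("conflict", sc$flags)))
    ## partition property on simulated cohorts
    expect_equal(nrow(sc), nrow(co$clinical))
    expect_false(any(is.na(sc$label)))
  }
})

test_that("a single trivial case yields a one-call cohort", {
  co <- mini_cohort("A", variants = variant_row("A", "STAG2", "truncating"))
  sc <- classify_cohort(co)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$label, "G7_Other")
})
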