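test_that("Kaplan-Meier matches the closed form without censoring", {
  km <- km_fit(1:4, rep(1, 4))
  expect_equal(km$survival, c(1, 0.75, 0.5, 0.25, 0))
  expect_equal(km$times, 0:4)
  km <- km_fit(5, 1)
  expect_equal(landmark_survival(km, 5), 0)
  ## general oracle: 1 - ECDF at every observed time
  set.seed(11)
  t <- round(rexp(300, 0.1), 2)
  km <- km_fit(t, rep(1, 300))
  ec <- ecdf(t)
  expect_equal(km$survival[-1], 1 - ec(km$times[-1]), tolerance = 1e-12)
})

test_that("all-censored input gives a flat curve with undefined median", {
  km <- km_fit(c(3, 8, 12), c(0, 0, 0))
  expect_true(all(km$survival == 1))
  expect_true(is.na(km_median(km)))
})

test_that("KM recovers an exponential distribution", {
  lam <- 0.08
  med <- log(2) / lam
  dev <- vapply(1:5, function(s) {
    set.seed(20 + s)
    km <- km_fit(rexp(2000, lam), rep(1, 2000))
    abs(landmark_survival(km, med) - exp(-lam * med))
  }, numeric(1))
  expect_lt(mean(dev), 0.02)   # sampling envelope at n = 2000
  est <- vapply(1:5, function(s) {
    set.seed(30 + s)
    km_median(km_fit(rexp(500, log(2) / 20), rep(1, 500)))
  }, numeric(1))
  expect_gte(mean(est), 18); expect_lte(mean(est), 22)
})

test_that("median is the first time survival reaches one half", {
  km <- list(times = c(0, 6, 12, 18), survival = c(1, 0.8, 0.5, 0.2),
             at_risk = c(10, 10, 8, 4), events = c(0, 2, 3, 3))
  class(km) <- "km_curve"
  expect_equal(km_median(km), 12)
})

test_that("landmark survival uses step interpolation", {
  km <- km_fit(c(2, 4, 9, 30), c(1, 1, 1, 0))
  expect_equal(landmark_survival(km, 0), 1)
  expect_equal(landmark_survival(km, 3), 0.75)
  expect_equal(landmark_survival(km, 100), landmark_survival(km, 30))
  ## a cohort with 621 of 1000 deaths before one year lands at 0.379
  t <- c(seq(0.1, 11.9, length.out = 621), rep(24, 379))
  km <- km_fit(t, c(rep(1, 621), rep(0, 379)))
  expect_equal(landmark_survival(km, 12), 0.379)
})

test_that("log-rank behaves at its boundaries and under rescaling", {
  g1 <- data.frame(time = c(3, 6, 9, 14, 20), event = c(1, 1, 0, 1, 1))
  same <- logrank_test(c(g1$time, g1$time), c(g1$event, g1$event),
                       rep(c("a", "b"), each = 5))
  expect_lt(same$chi_square, 1e-10)
  expect_gt(same$p_value, 0.99)
  set.seed(5)
  t <- c(rexp(40, 0.2), rexp(40, 0.05)); ev <- rep(1, 80)
  grp <- rep(c("a", "b"), each = 40)
  lr1 <- logrank_test(t, ev, grp)
  lr2 <- logrank_test(t * 12, ev, grp)
  expect_equal(lr1$chi_square, lr2$chi_square)
  expect_error(logrank_test(1:3, rep(1, 3), rep("a", 3)), "at least 2 groups")
  expect_error(
    logrank_test(1:4, rep(1, 4),
                 factor(rep(c("a", "b"), 2), levels = c("a", "b", "c"))),
    "group with zero records")
})

test_that("log-rank detects a 14 vs 5 month separation with good power", {
  rej <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    t <- c(rexp(60, log(2) / 14), rexp(60, log(2) / 5))
    logrank_test(t, rep(1, 120), rep(c("a", "b"), each = 60))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("demographic summaries follow the stated conventions", {
  b <- fixture_bundle()
  ds <- demographic_summary(b$co, b$sc)
  idh <- ds$by_subgroup[ds$by_subgroup$subgroup == "IDH", ]
  expect_equal(idh$age_mean, 42)          # mean and median coincide at 42
  expect_equal(idh$age_median, 42)
  expect_equal(idh$mf_ratio, 0)           # all-female IDH-mutant subgroup
  ## constant ages give SEM 0
  co <- mini_cohort(clinical = blank_clinical(c("A", "B", "C")))
  co$clinical$age <- 42L
  sc <- suppressWarnings(classify_cohort(co))
  ds1 <- demographic_summary(co, sc)
  expect_equal(ds1$by_subgroup$age_sem, 0)
  ## 11 M / 7 F is a 1.57 ratio
  co <- mini_cohort(clinical = blank_clinical(sprintf("C%02d", 1:18)))
  co$clinical$sex <- rep(c("M", "F"), c(11, 7))
  ds2 <- demographic_summary(co, suppressWarnings(classify_cohort(co)))
  expect_equal(round(ds2$by_subgroup$mf_ratio, 2), 1.57)
  ## missing ethnicity drops out of the ratio denominator
  co$clinical$ethnicity <- c(rep("White", 10), rep("Black", 3), rep(NA, 5))
  ds3 <- demographic_summary(co, suppressWarnings(classify_cohort(co)))
  expect_equal(ds3$by_subgroup$white, 10)
  expect_equal(ds3$by_subgroup$black, 3)
  ## age tests carry raw and Holm-adjusted columns
  expect_true(all(c("p_value", "p_holm") %in% names(ds$age_tests)))
  expect_true(all(ds$age_tests$p_holm >= ds$age_tests$p_value, na.rm = TRUE))
})

test_that("KM curves export as TSV", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_km_curve(km, p)
  df <- read.delim(p)
  expect_equal(df$survival, km$survival)
  expect_equal(df$at_risk, km$at_risk)
})
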