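test_that("proliferation score is the mean fold over present markers", {
  expect_equal(proliferation_score(c(MKI67 = 3.0)), 3.0)
  expect_equal(proliferation_score(c(MKI67 = 2, PCNA = 4),
                                   marker_genes = c("MKI67", "PCNA")), 3.0)
  expect_true(is.na(proliferation_score(c(EGFR = 10))))
})

test_that("correlation matrix is a valid Pearson matrix with guards", {
  v <- cbind(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5), d = c(5, 3, 2, 1))
  cm <- correlation_matrix(v)
  expect_equal(diag(cm), c(a = 1, b = 1, d = 1))
  expect_equal(cm, t(cm))
  expect_equal(cm["a", "b"], 1)
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  ## mean-centered mirrored vector correlates at -1
  v2 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(correlation_matrix(v2)["a", "b"], -1)
  expect_error(correlation_matrix(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "zero-variance feature vector for subgroup: a")
  expect_error(correlation_matrix(v[, 1, drop = FALSE]), "at least 2")
  expect_error(correlation_matrix(v[1:2, ]), "at least 3")
})

test_that("two subgroups join at height one minus their correlation", {
  v <- cbind(a = c(1, 2, 3, 7), b = c(2, 1, 4, 6))
  r <- correlation_matrix(v)["a", "b"]
  hc <- cluster_subgroups(correlation_matrix(v))
  expect_equal(hc$height, 1 - r)
})

test_that("clustering is invariant to input order and feature scaling", {
  b <- fixture_bundle()
  fv <- subgroup_feature_vectors(b$fm, b$co, b$sc)
  hc1 <- cluster_subgroups(correlation_matrix(fv))
  hc2 <- cluster_subgroups(correlation_matrix(fv[, rev(colnames(fv))]))
  expect_equal(cut_groups(hc1, 4), cut_groups(hc2, 4))
  expect_equal(sort(hc1$height), sort(hc2$height))
  hc3 <- cluster_subgroups(correlation_matrix(fv * 10))
  expect_equal(cut_groups(hc1, 4), cut_groups(hc3, 4))
  ## merge heights never decrease toward the root
  expect_false(is.unsorted(hc1$height))
})

test_that("the fixture reproduces the reference subgroup clustering structure", {
  b <- fixture_bundle()
  fv <- subgroup_feature_vectors(b$fm, b$co, b$sc)
  expect_true(all(c("CDK6_fold", "proliferation") %in% rownames(fv)))
  cm <- correlation_matrix(fv)
  ## EGFR-amplified and NF1 share the highest off-diagonal correlation
  ## among the IDH-wild-type subgroups
  wt <- setdiff(colnames(cm), "IDH")
  off <- cm[wt, wt]; diag(off) <- NA
  top <- which(off == max(off, na.rm = TRUE), arr.ind = TRUE)
  expect_setequal(rownames(off)[top[, 1]], c("EGFR_amp", "NF1"))

  has_subtree <- function(hc, labels) {
    any(vapply(seq_len(ncol(cm) - 1), function(k)
      any(vapply(cut_groups(hc, k), identical, logical(1),
                 y = sort(labels))), logical(1)))
  }
  for (lk in c("average", "complete")) {
    hc <- cluster_subgroups(cm, lk)
    expect_true(has_subtree(hc, c("EGFR_amp", "NF1", "RAF")), info = lk)
    expect_true(has_subtree(hc, c("MultiRTK", "Other")), info = lk)
  }
  ## complete linkage reproduces the full first cluster with FGFR3; under
  ## average linkage FGFR3 attaches elsewhere -- a logged discrepancy
  hc_c <- cluster_subgroups(cm, "complete")
  expect_true(has_subtree(hc_c, c("EGFR_amp", "NF1", "RAF", "FGFR3")))
  hc_a <- cluster_subgroups(cm, "average")
  if (!has_subtree(hc_a, c("EGFR_amp", "NF1", "RAF", "FGFR3")))
    message("average linkage: FGFR3 does not join the EGFR/NF1/RAF subtree ",
            "(known divergence from the complete-linkage structure)")
  ## PDGFRA, EGFRm and IDH segregate from the first cluster
  for (k in 2:6) for (g in cut_groups(hc_c, k))
    if (all(c("EGFR_amp", "NF1") %in% g))
      expect_false(any(c("PDGFRA", "EGFR_mut", "IDH") %in% g) &&
                     !setequal(g, colnames(cm)))
})

test_that("dendrograms export to Newick with merge-height branch lengths", {
  b <- fixture_bundle()
  fv <- subgroup_feature_vectors(b$fm, b$co, b$sc)
  hc <- cluster_subgroups(correlation_matrix(fv))
  p <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, p)
  tr <- ape::read.tree(p)
  expect_setequal(tr$tip.label, colnames(fv))
  expect_equal(max(ape::node.depth.edgelength(tr)), max(hc$height) / 2,
               tolerance = 1e-6)
})
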