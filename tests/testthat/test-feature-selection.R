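test_that("univariate rankings find perfect separation and null features", {
  tab <- spiked_table(10, 10, n_noise = 5, d = 50, seed = 2)
  st <- univariate_stats(tab)
  expect_equal(st$univariate_auc$label[1], "spike")
  expect_equal(st$univariate_auc$score[1], 1)
  expect_equal(st$ttest$label[1], "spike")

  # permuted labels: mean per-feature AUC ~ 0.5
  set.seed(11)
  null_tab <- spiked_table(10, 10, n_noise = 999, d = 0, seed = 12)
  st0 <- univariate_stats(null_tab)
  expect_equal(mean(st0$univariate_auc$auc), 0.5, tolerance = 0.02)

  # zero shift -> zero fold change
  raw <- tiny_table(6, 4, seed = 3)
  raw$abundances <- matrix(rep(c(1, 2, 4, 8), each = 6), 6)
  colnames(raw$abundances) <- raw$features$feature_id
  sc <- glog_transform(raw)
  sc$transform_state <- "autoscaled"
  fc <- univariate_stats(sc, raw_table = raw)$fold_change
  expect_equal(fc$log2_fc, rep(0, 4))

  one_group <- tab
  one_group$samples$group <- "case"
  expect_error(univariate_stats(one_group), "two sample groups")
})

test_that("lasso frequency finds the spike, zeroes constants, is reproducible", {
  tab <- spiked_table(40, 40, n_noise = 50, d = 3, seed = 1)
  tab$abundances[, "noise001"] <- 0  # constant feature
  freq <- lasso_selection_frequency(tab, n_subsamples = 50, seed = 7)
  expect_equal(freq$label[1], "spike")
  expect_gte(freq$score[1], 90)
  expect_equal(freq$score[freq$label == "noise001"], 0)
  again <- lasso_selection_frequency(tab, n_subsamples = 50, seed = 7)
  expect_identical(as.data.frame(freq), as.data.frame(again))
  expect_error(lasso_selection_frequency(tab, n_subsamples = 5), "10")
})

test_that("SVM-RFE ranks the spike at the top deterministically", {
  for (seed in 1:3) {
    tab <- spiked_table(30, 30, n_noise = 60, d = 3, seed = seed)
    r <- linear_svm_ranking(tab, seed = seed)
    expect_lte(which(r$label == "spike"), 10)
  }
  tab <- spiked_table(30, 30, n_noise = 40, d = 3, seed = 9)
  r1 <- linear_svm_ranking(tab, seed = 4)
  r2 <- linear_svm_ranking(tab, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # duplicated feature columns end up adjacent (tied weights)
  dup <- tab
  dup$abundances[, "noise001"] <- dup$abundances[, "spike"]
  rd <- linear_svm_ranking(dup, seed = 4)
  expect_lte(abs(which(rd$label == "spike") -
                   which(rd$label == "noise001")), 1)

  small <- spiked_table(4, 4, n_noise = 5, d = 3, seed = 2)
  expect_warning(linear_svm_ranking(small), "without RFE")
})

test_that("PLS-DA VIP satisfies its normalization identity and finds the spike", {
  tab <- spiked_table(30, 30, n_noise = 40, d = 3, seed = 5)
  v <- plsda_vip(tab)
  expect_equal(mean(v$score^2), 1, tolerance = 1e-9)
  expect_equal(v$label[1], "spike")
  expect_warning(plsda_vip(spiked_table(3, 3, n_noise = 50, d = 1),
                           n_components = 10), "reducing")
})

test_that("random-forest importance finds the spike and is seed-stable", {
  tab <- spiked_table(30, 30, n_noise = 40, d = 3, seed = 6)
  r <- random_forest_importance(tab, n_trees = 300, seed = 8)
  expect_lte(which(r$label == "spike"), 10)
  r2 <- random_forest_importance(tab, n_trees = 300, seed = 8)
  expect_identical(as.data.frame(r), as.data.frame(r2))
})

test_that("rankings are invariant to feature-column permutation", {
  tab <- spiked_table(20, 20, n_noise = 30, d = 2, seed = 10)
  perm <- sample(ncol(tab$abundances))
  tab2 <- feature_table(tab$samples, tab$features[perm, , drop = FALSE],
                        tab$abundances[, perm, drop = FALSE], "autoscaled")
  a <- univariate_stats(tab)$univariate_auc
  b <- univariate_stats(tab2)$univariate_auc
  expect_equal(as.data.frame(a), as.data.frame(b))
  va <- plsda_vip(tab)
  vb <- plsda_vip(tab2)
  expect_equal(va$score[match(va$label, vb$label)], va$score,
               tolerance = 1e-9)
})

test_that("panels truncate and preserve rank order", {
  r <- ranked_feature_list(sprintf("m%02d_N", 1:294),
                           rev(seq_len(294)), "univariate_auc")
  p <- build_panel(r, 10)
  expect_length(p$labels, 10)
  expect_equal(p$labels, sprintf("m%02d_N", 1:10))
  expect_length(build_panel(r, 1)$labels, 1)
  expect_warning(pbig <- build_panel(r, 500), "exceeds")
  expect_length(pbig$labels, 294)
})

test_that("class whitelists restrict annotated tables before ranking", {
  lib <- builtin_panel_library()
  samples <- data.frame(sample_id = c("a", "b"), group = c("case", "control"))
  feats <- data.frame(
    feature_id = marker_labels,
    mz = expected_mz(lib$records$monoisotopic_mass,
                     lib$records$expected_mode),
    esi_mode = lib$records$expected_mode,
    annotation = lib$records$name, stringsAsFactors = FALSE)
  tab <- feature_table(samples, feats, matrix(1:12, 2))
  fa_only <- filter_by_class(tab, lib, "FA")
  expect_equal(ncol(fa_only$abundances), 2)
  expect_true(all(grepl("^FA", fa_only$features$annotation)))
})
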