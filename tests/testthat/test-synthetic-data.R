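test_that("cohort simulation is seed-deterministic with the stated shapes", {
  cfg <- fast_config(seed = 5)
  a <- simulate_cohort(cfg, 1)
  b <- simulate_cohort(cfg, 1)
  expect_identical(a, b)
  expect_equal(nrow(a$samples), 27 + 36)
  expect_equal(sum(a$samples$group == "case"), 27)
  r <- simulate_cohort(cfg, 2)
  expect_equal(nrow(r$samples), 31 + 53)
  expect_false(identical(a$abundances[1, 1], r$abundances[1, 1]))
  expect_identical(a$transform_state, "raw")
  # both modes present, all m/z in scan range
  expect_setequal(unique(a$features$esi_mode), c("NEG", "POS"))
  expect_true(all(a$features$mz >= 50 & a$features$mz <= 1200))
})

test_that("all six markers are annotatable in both cohorts at 0.01 Da", {
  cfg <- fast_config(seed = 6)
  two <- simulate_two_cohorts(cfg)
  lib <- cfg$library
  for (tab in two) {
    ann <- annotate_table(tab, lib, 0.01)
    expect_true(all(marker_labels %in% ann$features$feature_id))
  }
  # dropout labels vanish from cohort 2 only
  ann2 <- annotate_table(two$replication, lib, 0.01)
  ann1 <- annotate_table(two$discovery, lib, 0.01)
  expect_true(all(default_dropout_labels() %in% ann1$features$feature_id))
  expect_false(any(default_dropout_labels() %in% ann2$features$feature_id))
  # noise features never annotate: reduction count is exact
  n_lib <- sum(!lib$records$is_drug_or_nonhuman)
  expect_equal(ncol(ann1$abundances), n_lib)
  expect_equal(ncol(ann2$abundances), n_lib - 4)
})

test_that("null effects give chance-level AUC, markers follow their directions", {
  null_cfg <- fast_config(seed = 7, n_noise = 30,
                          marker_effects = setNames(numeric(6),
                                                    names(default_marker_effects())))
  tab <- simulate_cohort(null_cfg, 1)
  sc <- autoscale(glog_transform(impute_missing(tab)))
  auc <- univariate_stats(sc)$univariate_auc
  expect_equal(mean(auc$auc), 0.5, tolerance = 0.03)

  # with defaults, spiked markers move in the configured direction
  cfg <- fast_config(seed = 8, n_noise = 30)
  ann <- annotate_table(simulate_cohort(cfg, 1), cfg$library, 0.01)
  raw <- ann
  sc2 <- autoscale(glog_transform(impute_missing(ann)))
  fc <- univariate_stats(sc2, raw_table = raw)$fold_change
  fc_sign <- sign(fc$log2_fc[match(marker_labels, fc$label)])
  expect_equal(fc_sign, sign(unname(default_marker_effects())))
})

test_that("marker AUC matches the binormal closed form at n = 500 + 500", {
  cfg <- synthetic_config(seed = 9, n_cases = c(500, 31),
                          n_controls = c(500, 53),
                          n_noise_features_per_mode = 0)
  tab <- annotate_table(simulate_cohort(cfg, 1), cfg$library, 0.01)
  sc <- autoscale(glog_transform(tab))
  auc <- univariate_stats(sc)$univariate_auc
  want <- theoretical_auc(1.5)
  got <- auc$auc[match(marker_labels, auc$label)]
  got[sign(default_marker_effects()) < 0] <-
    1 - got[sign(default_marker_effects()) < 0]
  expect_equal(got, rep(want, 6), tolerance = 0.02, ignore_attr = TRUE)
})

test_that("theoretical AUC follows the binormal formula", {
  expect_equal(theoretical_auc(0), 0.5)
  expect_equal(round(theoretical_auc(1.19), 2), 0.80)
  expect_equal(theoretical_auc(50), 1)
  expect_lt(theoretical_auc(-1), 0.5)
})

test_that("dropout recreates the 10-to-6 panel intersection", {
  cfg <- fast_config(seed = 10, n_noise = 30)
  two <- simulate_two_cohorts(cfg)
  ann2 <- annotate_table(two$replication, cfg$library, 0.01)
  panel10 <- panel_definition(c(marker_labels, default_dropout_labels()),
                              method = "linear_svm", k = 10)
  common <- suppressMessages(intersect_common(panel10, ann2))
  expect_length(common$labels, 6)
  expect_setequal(common$labels, marker_labels)
})

test_that("batch shift separates cohorts on PC1 until corrected", {
  cfg <- fast_config(seed = 12, n_noise = 40, batch_shift = 2,
                     dropout_labels = character(0))
  two <- simulate_two_cohorts(cfg)
  lib <- cfg$library
  glogged <- lapply(two, function(t) {
    glog_transform(impute_missing(annotate_table(t, lib, 0.01)))
  })
  sep <- function(tables) {
    stacked <- stack_cohorts(tables[[1]], tables[[2]])
    sc <- pca_scores(autoscale(stacked), 1)
    b <- stacked$samples$batch
    abs(mean(sc[b == "batch1", 1]) - mean(sc[b == "batch2", 1])) / sd(sc[, 1])
  }
  before <- sep(glogged)
  after <- sep(batch_correct(glogged))
  expect_lt(after, before)
  expect_gt(before, 1)   # batches clearly separate pre-correction
  expect_lt(after, 0.5)  # and mix afterwards
})
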