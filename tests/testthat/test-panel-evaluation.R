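test_that("logistic scores reproduce indicators, null panels, coefficients", {
  # a feature that equals the label indicator separates perfectly
  tab <- spiked_table(15, 15, n_noise = 2, d = 0, seed = 1)
  tab$abundances[, "spike"] <- rep(c(1, 0), c(15, 15))
  panel <- panel_definition("spike")
  ls <- logistic_scores(tab, panel)
  expect_true(ls$ridge_stabilized)
  roc <- roc_curve_auc(ls$scores, rep(c(1, 0), c(15, 15)))
  expect_equal(roc$auc, 1)

  # intercept-only panel: constant scores, AUC 0.5
  null_panel <- panel_definition(character(0))
  ls0 <- logistic_scores(tab, null_panel)
  expect_equal(length(unique(ls0$scores)), 1)
  expect_equal(roc_curve_auc(ls0$scores, rep(c(1, 0), c(15, 15)))$auc, 0.5)

  # large-sample coefficient recovery
  set.seed(21)
  n <- 5000
  x <- matrix(rnorm(2 * n), n, 2)
  eta <- -0.5 + 1.2 * x[, 1] - 0.8 * x[, 2]
  y <- rbinom(n, 1, plogis(eta))
  big <- feature_table(
    data.frame(sample_id = sprintf("s%04d", 1:n),
               group = ifelse(y == 1, "case", "control")),
    data.frame(feature_id = c("f1", "f2"), mz = c(100, 200),
               esi_mode = "NEG"),
    x, "autoscaled")
  fit <- logistic_scores(big, panel_definition(c("f1", "f2")))
  expect_equal(unname(fit$coefficients[2]), 1.2, tolerance = 0.12)
  expect_equal(unname(fit$coefficients[3]), -0.8, tolerance = 0.12)

  expect_error(logistic_scores(tab, panel_definition("absent_N")),
               "intersect_common")
})

test_that("ROC AUC matches brute force, handles ties, and builds valid curves", {
  expect_equal(roc_curve_auc(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve_auc(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc, 0.75)
  expect_equal(roc_curve_auc(rep(1, 8), rep(c(1, 0), 4))$auc, 0.5)
  expect_error(roc_curve_auc(1:4, rep(1, 4)), "both classes")

  set.seed(31)
  for (i in 1:30) {
    n <- sample(10:100, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # force some ties
    r <- roc_curve_auc(scores, labels)
    expect_equal(r$auc, bf_auc(scores, labels), tolerance = 1e-12)
    # monotone curve from (0,0) to (1,1)
    expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_true(all(diff(r$curve$fpr) >= 0))
    # invariance under strictly increasing transforms
    expect_equal(roc_curve_auc(exp(scores / 2), labels)$auc, r$auc)
    # Youden point is attainable and consistent
    expect_gte(r$sensitivity + r$specificity, 1)
  }
})

test_that("AUC and CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:10) {
    labels <- rep(c(1, 0), c(20, 25))
    scores <- rnorm(45) + labels
    ours <- roc_curve_auc(scores, labels)
    theirs <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
  }
})

test_that("pooled 10-fold CV is seeded, stratified, and honest on nulls", {
  tab <- spiked_table(20, 20, n_noise = 3, d = 50, seed = 51)
  panel <- panel_definition("spike")
  r1 <- evaluate_cv10(tab, panel, seed = 3)
  expect_equal(r1$auc, 1)
  expect_identical(r1$mode, "cv10")
  r2 <- evaluate_cv10(tab, panel, seed = 3)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$curve, r2$curve)

  expect_warning(evaluate_cv10(spiked_table(8, 12, 3, 1, seed = 6),
                               panel, seed = 1), "stratify")

  # permuted-label null: pooled CV AUC centred at 0.5
  set.seed(61)
  aucs <- replicate(40, {
    tab0 <- spiked_table(15, 15, n_noise = 3, d = 0,
                         seed = sample.int(1e6, 1))
    evaluate_cv10(tab0, panel_definition(c("spike", "noise001")),
                  seed = sample.int(1e6, 1))$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("cross-validated AUC does not exceed discovery AUC in expectation", {
  set.seed(71)
  deltas <- replicate(60, {
    tab <- spiked_table(15, 15, n_noise = 8, d = 0.8,
                        seed = sample.int(1e6, 1))
    panel <- panel_definition(c("spike", "noise001", "noise002"))
    evaluate_discovery(tab, panel)$auc -
      evaluate_cv10(tab, panel, seed = sample.int(1e6, 1))$auc
  })
  expect_gt(mean(deltas), 0)
})

test_that("replication refits on the external cohort and demands its labels", {
  tab <- spiked_table(20, 25, n_noise = 5, d = 1.5, seed = 81)
  panel <- panel_definition(c("spike", "noise001"))
  disc <- evaluate_discovery(tab, panel)
  repl <- evaluate_replication(tab, panel)
  expect_equal(repl$auc, disc$auc)
  expect_identical(repl$mode, "replication")
  expect_error(evaluate_replication(tab, panel_definition("ghost_N")),
               "intersect_common")
  # applying fixed discovery coefficients is available as an option
  fit <- logistic_scores(tab, panel)
  fixed <- evaluate_replication(tab, panel, apply_fitted = fit$coefficients)
  expect_equal(fixed$auc, disc$auc)
})
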