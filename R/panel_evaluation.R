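#' Fitted case probabilities from a logistic panel model
#'
#' Maximum-likelihood logistic regression of the case indicator on the
#' panel's features. If the fit separates perfectly (fitted probabilities
#' numerically 0 or 1), a weakly ridge-stabilized fit replaces it and the
#' result is flagged.
#'
#' @param table an autoscaled [feature_table()] containing the panel labels.
#' @param panel a [panel_definition()].
#' @param positive the case group label.
#' @param ridge_lambda penalty used by the stabilized fallback.
#' @return list with `scores` (named per-sample case probabilities),
#'   `coefficients` (including intercept), and `ridge_stabilized` flag.
#' @export
logistic_scores <- function(table, panel, positive = "case",
                            ridge_lambda = 0.05) {
  stopifnot(inherits(table, "feature_table"),
            inherits(panel, "panel_definition"))
  missing <- setdiff(panel$labels, colnames(table$abundances))
  if (length(missing)) {
    stop("panel label(s) absent from the table: ",
         paste(missing, collapse = ", "),
         "; run intersect_common() against this cohort first",
         call. = FALSE)
  }
  y <- .case_indicator(table, positive)
  x <- table$abundances[, panel$labels, drop = FALSE]
  if (length(panel$labels) == 0) {
    p <- rep(mean(y), length(y))
    return(list(scores = stats::setNames(p, table$samples$sample_id),
                coefficients = c(`(Intercept)` = stats::qlogis(mean(y))),
                ridge_stabilized = FALSE))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # a vanishing residual deviance is separation even when IRLS stops quietly
  if (!separated && fit$deviance < 1e-6) separated <- TRUE
  if (!separated) {
    coefs <- stats::setNames(fit$coefficients,
                             c("(Intercept)", panel$labels))
    p <- fit$fitted.values
  } else {
    # glmnet needs >= 2 columns; pad single-feature panels with a null column
    xr <- if (ncol(x) == 1) cbind(x, 0) else x
    rfit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
    coefs <- stats::setNames(as.numeric(stats::coef(rfit))[
      seq_len(ncol(x) + 1)], c("(Intercept)", panel$labels))
    eta <- as.numeric(cbind(1, x) %*% coefs)
    p <- stats::plogis(eta)
  }
  list(scores = stats::setNames(as.numeric(p), table$samples$sample_id),
       coefficients = coefs, ridge_stabilized = separated)
}

#' ROC curve and AUC with Hanley-McNeil inference
#'
#' AUC by the Mann-Whitney statistic (ties counted 0.5), standard error by
#' the Hanley-McNeil formula, 95% CI as `auc +/- 1.96 se` clipped to
#' \[0, 1\], and sensitivity/specificity at the Youden-optimal threshold
#' (ties broken toward higher specificity). A stratified-bootstrap CI is
#' available as an alternative.
#'
#' @param scores numeric classifier scores, larger = more case-like.
#' @param labels 0/1 case indicator (or logical) aligned with `scores`.
#' @param mode reporting context: `"discovery"`, `"cv10"` or
#'   `"replication"`.
#' @param bootstrap_ci if `TRUE`, replace the normal-approximation CI with a
#'   percentile CI from `n_boot` stratified bootstrap resamples.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return a `roc_result`: list with `auc`, `se`, `ci95`, `sensitivity`,
#'   `specificity`, `threshold`, `n_cases`, `n_controls`, `mode`, and
#'   `curve` (data.frame of monotone (FPR, TPR) points from (0,0) to
#'   (1,1)).
#' @export
roc_curve_auc <- function(scores, labels, mode = "discovery",
                          bootstrap_ci = FALSE, n_boot = 500, seed = 1) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  auc <- .mann_whitney_auc(scores, labels)
  se <- hanley_mcneil_se(auc, n1, n0)
  if (bootstrap_ci) {
    set.seed(seed)
    i1 <- which(labels == 1)
    i0 <- which(labels == 0)
    boots <- replicate(n_boot, {
      idx <- c(sample(i1, n1, replace = TRUE),
               sample(i0, n0, replace = TRUE))
      .mann_whitney_auc(scores[idx], labels[idx])
    })
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  } else {
    ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  }
  # stepwise curve over descending unique thresholds
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- curve[!duplicated(curve), , drop = FALSE]
  rownames(curve) <- NULL
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(fpr[best])]  # ties -> higher specificity
  structure(
    list(auc = auc, se = se, ci95 = ci,
         sensitivity = tpr[best], specificity = 1 - fpr[best],
         threshold = thr[best], n_cases = n1, n_controls = n0,
         mode = mode, curve = curve),
    class = "roc_result")
}

.mann_whitney_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Construct a minimal ROC result from summary numbers
#'
#' For comparisons whose inputs are published summary values (an AUC and the
#' group sizes) rather than raw scores — e.g. testing a replication AUC
#' against a printed internal-validation AUC.
#'
#' @param auc area under the ROC curve.
#' @param n_cases,n_controls group sizes behind the AUC.
#' @param mode reporting context label.
#' @return a `roc_result` carrying `auc`, Hanley-McNeil `se`, and the group
#'   sizes.
#' @export
roc_result <- function(auc, n_cases, n_controls, mode = "summary") {
  stopifnot(auc >= 0, auc <= 1)
  structure(
    list(auc = auc, se = hanley_mcneil_se(auc, n_cases, n_controls),
         ci95 = NULL, sensitivity = NA_real_, specificity = NA_real_,
         threshold = NA_real_, n_cases = n_cases, n_controls = n_controls,
         mode = mode, curve = NULL),
    class = "roc_result")
}

#' @method print roc_result
#' @export
print.roc_result <- function(x, ...) {
  ci <- if (is.null(x$ci95)) "" else
    sprintf(" (95%% CI %.3f-%.3f)", x$ci95[1], x$ci95[2])
  cat(sprintf("<roc_result> %s: AUC = %.3f%s, SE = %.4f, n = %d/%d\n",
              x$mode, x$auc, ci, x$se, x$n_cases, x$n_controls))
  if (!is.na(x$sensitivity)) {
    cat(sprintf("  sens/spec at Youden threshold: %.3f/%.3f\n",
                x$sensitivity, x$specificity))
  }
  invisible(x)
}

#' Training/discovery ROC of a panel
#'
#' Full-data logistic fit and ROC on the discovery cohort.
#'
#' @inheritParams logistic_scores
#' @param ... passed to [roc_curve_auc()].
#' @return a `roc_result` with `mode = "discovery"`.
#' @export
evaluate_discovery <- function(table, panel, positive = "case", ...) {
  ls <- logistic_scores(table, panel, positive)
  roc_curve_auc(ls$scores, .case_indicator(table, positive),
                mode = "discovery", ...)
}

#' Internal validation: pooled 10-fold cross-validated ROC
#'
#' Seeded stratified split into `folds` folds; the logistic model is refit
#' on each training 9/10 and the held-out case probabilities are pooled into
#' a single ROC curve (one internal-validation AUC per panel, rather than
#' an average of per-fold AUCs).
#'
#' @inheritParams logistic_scores
#' @param seed integer seed; fold assignment and AUC are reproducible.
#' @param folds number of folds (default 10); reduced with a warning when
#'   the smaller class cannot stratify.
#' @param ... passed to [roc_curve_auc()].
#' @return a `roc_result` with `mode = "cv10"`.
#' @export
evaluate_cv10 <- function(table, panel, seed = 1, folds = 10,
                          positive = "case", ...) {
  stopifnot(inherits(table, "feature_table"),
            inherits(panel, "panel_definition"))
  y <- .case_indicator(table, positive)
  n_min <- min(sum(y == 1), sum(y == 0))
  if (n_min < folds) {
    warning("smallest class (", n_min, ") cannot stratify ", folds,
            " folds; using ", n_min, call. = FALSE)
    folds <- n_min
  }
  set.seed(seed)
  fold_idx <- .stratified_folds(y, folds)
  p <- numeric(length(y))
  for (f in seq_along(fold_idx)) {
    test <- fold_idx[[f]]
    train_tab <- feature_table(table$samples[-test, , drop = FALSE],
                               table$features,
                               table$abundances[-test, , drop = FALSE],
                               table$transform_state)
    fit <- logistic_scores(train_tab, panel, positive)
    eta <- as.numeric(cbind(1, table$abundances[test, panel$labels,
                                                drop = FALSE]) %*%
                        fit$coefficients)
    p[test] <- stats::plogis(eta)
  }
  roc_curve_auc(p, y, mode = "cv10", ...)
}

#' External replication ROC of a fixed panel
#'
#' Refits the logistic coefficients on the external cohort (the replication
#' convention used here) and reports the full-data ROC. Set
#' `apply_fitted` to a coefficient vector from the discovery fit to instead
#' apply the discovery model unchanged, as a sensitivity analysis.
#'
#' @param table_external an annotated, autoscaled external-cohort
#'   [feature_table()] containing all panel labels.
#' @inheritParams logistic_scores
#' @param apply_fitted optional named coefficient vector
#'   (intercept + panel labels) to apply instead of refitting.
#' @param ... passed to [roc_curve_auc()].
#' @return a `roc_result` with `mode = "replication"`.
#' @export
evaluate_replication <- function(table_external, panel, positive = "case",
                                 apply_fitted = NULL, ...) {
  stopifnot(inherits(table_external, "feature_table"),
            inherits(panel, "panel_definition"))
  if (is.null(apply_fitted)) {
    ls <- logistic_scores(table_external, panel, positive)
    scores <- ls$scores
  } else {
    x <- table_external$abundances[, panel$labels, drop = FALSE]
    scores <- stats::plogis(as.numeric(cbind(1, x) %*% apply_fitted))
  }
  roc_curve_auc(scores, .case_indicator(table_external, positive),
                mode = "replication", ...)
}
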