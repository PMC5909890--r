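#' Construct a ranked feature list
#'
#' @param labels feature labels, unique.
#' @param scores numeric ranking scores (higher = stronger candidate).
#' @param method label of the producing selector.
#' @param seed integer seed used (NA for deterministic selectors).
#' @param extra optional data.frame of per-feature side information, aligned
#'   with `labels` before ranking.
#' @return a `ranked_feature_list`: data.frame `(label, score, ...)` sorted
#'   by non-increasing score.
#' @export
ranked_feature_list <- function(labels, scores, method, seed = NA_integer_,
                                extra = NULL) {
  stopifnot(length(labels) == length(scores), !anyDuplicated(labels))
  df <- data.frame(label = as.character(labels), score = as.numeric(scores),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  df <- df[order(-df$score, df$label), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, method = method, seed = seed,
            class = c("ranked_feature_list", "data.frame"))
}

#' Construct a panel definition
#'
#' @param labels ordered `Name_Mode` analyte labels.
#' @param method label of the selection method that produced the panel.
#' @param k the nominal panel size the selection aimed for.
#' @return a `panel_definition`.
#' @export
panel_definition <- function(labels, method = "manual",
                             k = length(labels)) {
  labels <- as.character(labels)
  stopifnot(!anyDuplicated(labels))
  structure(list(labels = labels, method = method, k = k),
            class = "panel_definition")
}

#' @method print panel_definition
#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("<panel_definition> %s, %d analyte(s):\n  %s\n",
              x$method, length(x$labels), paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Take the top-k of a ranked list as a panel
#'
#' The workflow's a-priori choice is the top ten analytes from each
#' discovery selector; refinement to smaller panels happens downstream via
#' [intersect_common()] and re-evaluation.
#'
#' @param ranked a [ranked_feature_list()].
#' @param k panel size (default 10); a `k` beyond the list length truncates
#'   with a warning.
#' @return a [panel_definition()].
#' @export
build_panel <- function(ranked, k = 10) {
  stopifnot(inherits(ranked, "ranked_feature_list"), k >= 1)
  if (k > nrow(ranked)) {
    warning("k = ", k, " exceeds the ", nrow(ranked),
            " ranked features; using all of them", call. = FALSE)
    k <- nrow(ranked)
  }
  panel_definition(ranked$label[seq_len(k)],
                   method = attr(ranked, "method"), k = k)
}

# Mann-Whitney AUC per feature column: P(case score > control score), ties 0.5
.column_auc <- function(x, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  apply(x, 2, function(col) {
    r <- rank(col)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
}

#' Univariate per-feature rankings: ROC AUC, Welch t, fold change
#'
#' The single-analyte rankings of the panel-refinement step: per-feature
#' Mann-Whitney AUC (folded to >= 0.5 for ranking), Welch two-sample t
#' statistic, and mean log2 fold change (case over control, computed on the
#' raw scale).
#'
#' @param table an autoscaled [feature_table()] used for the AUC and t
#'   rankings.
#' @param raw_table the corresponding raw-scale table for the fold-change
#'   ranking; may be omitted, in which case only AUC and t are returned.
#' @param positive the case group label.
#' @return named list of [ranked_feature_list()]s: `univariate_auc`,
#'   `ttest`, and (when `raw_table` is given) `fold_change`. The AUC list
#'   carries the unfolded AUC in an `auc` column; the fold-change list
#'   carries the signed log2 FC in `log2_fc`.
#' @export
univariate_stats <- function(table, raw_table = NULL, positive = "case") {
  stopifnot(inherits(table, "feature_table"))
  y <- .case_indicator(table, positive)
  if (min(sum(y == 1), sum(y == 0)) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  x <- table$abundances
  auc <- .column_auc(x, y)
  folded <- pmax(auc, 1 - auc)
  m1 <- colMeans(x[y == 1, , drop = FALSE])
  m0 <- colMeans(x[y == 0, , drop = FALSE])
  v1 <- apply(x[y == 1, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[y == 0, , drop = FALSE], 2, stats::var)
  tstat <- (m1 - m0) / sqrt(v1 / sum(y == 1) + v0 / sum(y == 0))
  tstat[!is.finite(tstat)] <- 0
  out <- list(
    univariate_auc = ranked_feature_list(
      colnames(x), folded, "univariate_auc",
      extra = data.frame(auc = auc)),
    ttest = ranked_feature_list(colnames(x), abs(tstat), "ttest",
                                extra = data.frame(t = tstat))
  )
  if (!is.null(raw_table)) {
    stopifnot(inherits(raw_table, "feature_table"))
    if (raw_table$transform_state != "raw") {
      stop("raw_table must be on the raw scale for fold change",
           call. = FALSE)
    }
    common <- intersect(colnames(x), colnames(raw_table$abundances))
    xr <- raw_table$abundances[, common, drop = FALSE]
    yr <- .case_indicator(raw_table, positive)
    fc <- log2(pmax(colMeans(xr[yr == 1, , drop = FALSE]), .Machine$double.eps) /
                 pmax(colMeans(xr[yr == 0, , drop = FALSE]), .Machine$double.eps))
    out$fold_change <- ranked_feature_list(
      common, abs(fc), "fold_change", extra = data.frame(log2_fc = fc))
  }
  out
}

#' LASSO selection frequency over stratified subsamples
#'
#' Stability selection: for each of `n_subsamples` stratified draws of
#' `subsample_fraction` of every group, an L1-penalized logistic regression
#' is fit with the penalty chosen by internal cross-validation (the 1-SE
#' rule); each feature's frequency is the percentage of draws in which its
#' coefficient is nonzero.
#'
#' @param table an autoscaled [feature_table()].
#' @param n_subsamples number of subsample draws (default 100; at least 10).
#' @param subsample_fraction fraction of each group drawn (default 0.8).
#' @param seed integer RNG seed; same inputs and seed give identical
#'   frequencies.
#' @param positive the case group label.
#' @param nfolds folds for the internal `cv.glmnet`.
#' @return a [ranked_feature_list()] of frequencies in percent (0-100).
#' @export
lasso_selection_frequency <- function(table, n_subsamples = 100,
                                      subsample_fraction = 0.8, seed = 1,
                                      positive = "case", nfolds = 5) {
  stopifnot(inherits(table, "feature_table"), n_subsamples >= 10)
  y <- .case_indicator(table, positive)
  x <- table$abundances
  set.seed(seed)
  count <- stats::setNames(numeric(ncol(x)), colnames(x))
  i1 <- which(y == 1)
  i0 <- which(y == 0)
  k1 <- max(2, round(subsample_fraction * length(i1)))
  k0 <- max(2, round(subsample_fraction * length(i0)))
  for (b in seq_len(n_subsamples)) {
    for (attempt in 1:10) {
      idx <- c(sample(i1, k1), sample(i0, k0))
      if (length(unique(y[idx])) == 2) break
      if (attempt == 10) stop("could not draw a two-class subsample",
                              call. = FALSE)
    }
    fit <- glmnet::cv.glmnet(x[idx, , drop = FALSE], y[idx],
                             family = "binomial", nfolds = nfolds,
                             standardize = FALSE)
    beta <- as.numeric(stats::coef(fit, s = "lambda.1se"))[-1]
    count <- count + (beta != 0)
  }
  ranked_feature_list(colnames(x), 100 * count / n_subsamples,
                      "lasso_frequency", seed = seed)
}

#' Linear-SVM recursive feature elimination ranking
#'
#' Fits a linear-kernel max-margin classifier, scores features by the
#' squared weight-vector components, and recursively eliminates the
#' lowest-weighted tenth until none remain; features are ranked by how long
#' they survive (last-surviving = top). The cost parameter is fixed once by
#' internal cross-validation on the full feature set.
#'
#' @param table an autoscaled [feature_table()].
#' @param seed integer RNG seed (cross-validation folds).
#' @param costs candidate SVM cost values for the inner CV.
#' @param positive the case group label.
#' @return a [ranked_feature_list()]; the score is the elimination-order
#'   index (larger = eliminated later).
#' @export
linear_svm_ranking <- function(table, seed = 1,
                               costs = c(0.01, 0.1, 1, 10),
                               positive = "case") {
  stopifnot(inherits(table, "feature_table"))
  y <- factor(.case_indicator(table, positive))
  x <- table$abundances
  set.seed(seed)
  svm_weights <- function(xm) {
    fit <- e1071::svm(xm, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    stats::setNames(w^2, colnames(xm))
  }
  if (nrow(x) < 10) {
    warning("fewer than 10 samples: single linear-SVM fit without RFE",
            call. = FALSE)
    cost <- 1
    w2 <- svm_weights(x)
    return(ranked_feature_list(names(w2), w2, "linear_svm", seed = seed))
  }
  # inner 5-fold CV accuracy to fix the cost once
  folds <- .stratified_folds(as.integer(as.character(y)), 5)
  acc <- vapply(costs, function(cc) {
    correct <- 0
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      fit <- e1071::svm(x[-test, , drop = FALSE], y[-test],
                        kernel = "linear", cost = cc, scale = FALSE)
      correct <- correct + sum(stats::predict(fit, x[test, , drop = FALSE]) ==
                                 y[test])
    }
    correct / length(y)
  }, numeric(1))
  cost <- costs[which.max(acc)]

  remaining <- colnames(x)
  elim_rank <- stats::setNames(numeric(ncol(x)), colnames(x))
  step <- 0
  while (length(remaining) > 0) {
    step <- step + 1
    w2 <- svm_weights(x[, remaining, drop = FALSE])
    n_drop <- max(1, floor(length(remaining) * 0.1))
    drop <- names(sort(w2))[seq_len(n_drop)]
    # within an elimination step, weaker weights rank lower
    ord <- order(w2[drop])
    elim_rank[drop[ord]] <- step + seq_along(drop) / (length(drop) + 1)
    remaining <- setdiff(remaining, drop)
  }
  ranked_feature_list(names(elim_rank), elim_rank, "linear_svm", seed = seed)
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Partial least squares discriminant analysis on the group indicator; VIP
#' scores from the final component (cumulative over components) rank the
#' features. The VIP normalization identity holds: the mean squared VIP
#' equals 1.
#'
#' @param table an autoscaled [feature_table()].
#' @param n_components number of PLS components (default 2; reduced with a
#'   warning when the matrix rank cannot support it).
#' @param positive the case group label.
#' @return a [ranked_feature_list()] of VIP scores.
#' @export
plsda_vip <- function(table, n_components = 2, positive = "case") {
  stopifnot(inherits(table, "feature_table"))
  y <- factor(ifelse(.case_indicator(table, positive) == 1, "case",
                     "control"))
  x <- table$abundances
  max_comp <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_comp) {
    warning("reducing n_components to the matrix rank bound ", max_comp,
            call. = FALSE)
    n_components <- max_comp
  }
  fit <- mixOmics::plsda(x, y, ncomp = n_components)
  v <- mixOmics::vip(fit)
  ranked_feature_list(rownames(v), v[, n_components], "plsda_vip")
}

#' Random-forest permutation importance ranking
#'
#' @param table an autoscaled [feature_table()].
#' @param n_trees number of trees (default 500).
#' @param seed integer RNG seed; rankings are seed-deterministic.
#' @param positive the case group label.
#' @return a [ranked_feature_list()] of mean-decrease-in-accuracy
#'   (permutation) importances.
#' @export
random_forest_importance <- function(table, n_trees = 500, seed = 1,
                                     positive = "case") {
  stopifnot(inherits(table, "feature_table"))
  y <- factor(.case_indicator(table, positive))
  x <- table$abundances
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  ranked_feature_list(names(imp), imp, "random_forest", seed = seed)
}

#' Filter a table to a compound-class whitelist
#'
#' Implements targeted-panel selection variants: restricts an annotated
#' table to features whose library compound class is in a whitelist (e.g.
#' the classes covered by a targeted kit) before ranking.
#'
#' @param table an annotated [feature_table()].
#' @param library the [compound_library()] used for annotation.
#' @param classes character vector of allowed `compound_class` values.
#' @return the filtered [feature_table()].
#' @export
filter_by_class <- function(table, library, classes) {
  stopifnot(inherits(table, "feature_table"),
            inherits(library, "compound_library"))
  cls <- library$records$compound_class[
    match(table$features$annotation, library$records$name)]
  keep <- !is.na(cls) & cls %in% classes
  feature_table(table$samples, table$features[keep, , drop = FALSE],
                table$abundances[, keep, drop = FALSE],
                table$transform_state)
}

# stratified fold assignment: list of test-index vectors
.stratified_folds <- function(y, n_folds) {
  folds <- vector("list", n_folds)
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    grp <- rep(seq_len(n_folds), length.out = length(idx))
    for (f in seq_len(n_folds)) {
      folds[[f]] <- c(folds[[f]], idx[grp == f])
    }
  }
  folds
}
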