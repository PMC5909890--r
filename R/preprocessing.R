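#' Generalized logarithm transform
#'
#' Variance-stabilizing transform applied elementwise to raw abundances:
#' \deqn{x \mapsto \log_2\left(\frac{x + \sqrt{x^2 + a^2}}{2}\right)}
#' It is strictly increasing, finite at zero (`glog(0) = log2(a/2)`) and
#' converges to `log2(x)` for `x >> a`.
#'
#' @param table a raw [feature_table()].
#' @param a positive transform offset on the relative-abundance scale
#'   (default 1). The exact offset only shifts the monotone scale; it is
#'   recorded in the transform parameters.
#' @return the table with `transform_state = "glog"`.
#' @export
glog_transform <- function(table, a = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(a) || length(a) != 1 || a <= 0) {
    stop("glog offset 'a' must be a positive scalar", call. = FALSE)
  }
  if (table$transform_state != "raw") {
    stop("glog_transform expects a raw table (state is '",
         table$transform_state, "')", call. = FALSE)
  }
  x <- table$abundances
  table$abundances <- log2((x + sqrt(x^2 + a^2)) / 2)
  table$transform_state <- "glog"
  attr(table, "transform_params") <- list(glog_a = a)
  table
}

#' Auto-scale a glog-transformed table
#'
#' Per-feature standardization: subtract the feature mean and divide by the
#' sample standard deviation (n-1 denominator). Zero-variance features are
#' dropped with a warning. The fitted means/sds are recorded so the same
#' scaling can be reapplied, though replication cohorts are normally scaled
#' with their own fitted parameters.
#'
#' @param table a glog-state [feature_table()] (an already autoscaled table
#'   passes through unchanged, making the operation idempotent).
#' @param params optional transform parameters from a previous fit whose
#'   `scale_means` / `scale_sds` should be applied instead of refitting.
#' @return the table with `transform_state = "autoscaled"` and an updated
#'   `"transform_params"` attribute.
#' @export
autoscale <- function(table, params = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (table$transform_state == "autoscaled" && is.null(params)) return(table)
  if (table$transform_state == "raw") {
    stop("autoscale expects a glog-transformed table; call glog_transform first",
         call. = FALSE)
  }
  x <- table$abundances
  if (nrow(x) < 2) stop("autoscaling needs at least 2 samples", call. = FALSE)
  if (is.null(params)) {
    mu <- colMeans(x)
    sds <- apply(x, 2, stats::sd)
  } else {
    idx <- match(colnames(x), names(params$scale_means))
    if (anyNA(idx)) stop("supplied params do not cover all features",
                         call. = FALSE)
    mu <- params$scale_means[idx]
    sds <- params$scale_sds[idx]
  }
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " zero-variance feature(s): ",
            paste(utils::head(colnames(x)[!keep], 5), collapse = ", "),
            call. = FALSE)
  }
  x <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep], "-"),
             2, sds[keep], "/")
  tp <- attr(table, "transform_params")
  if (is.null(tp)) tp <- list()
  tp$scale_means <- stats::setNames(mu[keep], colnames(x))
  tp$scale_sds <- stats::setNames(sds[keep], colnames(x))
  out <- feature_table(table$samples,
                       table$features[keep, , drop = FALSE], x,
                       transform_state = "autoscaled")
  attr(out, "transform_params") <- tp
  out
}

#' Impute non-detects by the half-minimum rule
#'
#' Zeros in a raw table (LC-MS non-detects) are replaced by half the
#' feature's minimum positive abundance; features with no positive value at
#' all are dropped with a warning.
#'
#' @param table a raw [feature_table()].
#' @return the imputed raw table.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$transform_state != "raw") {
    stop("impute_missing operates on raw abundances", call. = FALSE)
  }
  x <- table$abundances
  all_zero <- apply(x, 2, function(col) all(col <= 0))
  if (any(all_zero)) {
    warning("dropping ", sum(all_zero), " all-zero feature(s): ",
            paste(utils::head(colnames(x)[all_zero], 5), collapse = ", "),
            call. = FALSE)
    x <- x[, !all_zero, drop = FALSE]
    table$features <- table$features[!all_zero, , drop = FALSE]
  }
  for (j in seq_len(ncol(x))) {
    zero <- x[, j] <= 0
    if (any(zero)) x[zero, j] <- min(x[!zero, j]) / 2
  }
  table$abundances <- x
  table
}

#' Per-feature location-scale batch adjustment
#'
#' For every feature shared by all tables (matched by `feature_id`), each
#' batch's values are recentred and rescaled to the pooled grand mean and
#' pooled standard deviation, computed on the current (glog) scale. After
#' adjustment the per-batch means of every shared feature are exactly equal.
#' Non-shared features pass through unchanged with a warning. Sample labels
#' and feature identity are never altered.
#'
#' @param tables list of >= 2 [feature_table()]s on the same transform
#'   scale, one per batch.
#' @return list of adjusted tables, in input order.
#' @export
batch_correct <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  for (t in tables) stopifnot(inherits(t, "feature_table"))
  states <- vapply(tables, function(t) t$transform_state, character(1))
  if (length(unique(states)) != 1) {
    stop("all tables must share a transform state", call. = FALSE)
  }
  shared <- Reduce(intersect, lapply(tables, function(t) t$features$feature_id))
  if (length(shared) == 0) {
    stop("batch correction needs at least one shared feature", call. = FALSE)
  }
  n_nonshared <- sum(vapply(tables, function(t) {
    sum(!t$features$feature_id %in% shared)
  }, numeric(1)))
  if (n_nonshared > 0) {
    warning(n_nonshared, " non-shared feature(s) passed through unadjusted",
            call. = FALSE)
  }
  # pooled grand mean (sample-weighted) and pooled within-batch sd, so that
  # identical batches are left exactly unchanged
  ns <- vapply(tables, function(t) nrow(t$samples), numeric(1))
  batch_means <- vapply(tables, function(t) {
    colMeans(t$abundances[, shared, drop = FALSE])
  }, numeric(length(shared)))
  batch_vars <- vapply(tables, function(t) {
    apply(t$abundances[, shared, drop = FALSE], 2, stats::var)
  }, numeric(length(shared)))
  if (length(shared) == 1) {
    batch_means <- matrix(batch_means, nrow = 1)
    batch_vars <- matrix(batch_vars, nrow = 1)
  }
  grand_mean <- as.vector(batch_means %*% ns / sum(ns))
  grand_sd <- sqrt(as.vector(batch_vars %*% (ns - 1) / sum(ns - 1)))
  names(grand_mean) <- names(grand_sd) <- shared
  lapply(tables, function(t) {
    x <- t$abundances[, shared, drop = FALSE]
    m <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    scale_fac <- ifelse(s > 0 & grand_sd > 0, grand_sd / s, 1)
    adj <- sweep(x, 2, m, "-")
    adj <- sweep(adj, 2, scale_fac, "*")
    adj <- sweep(adj, 2, grand_mean, "+")
    t$abundances[, shared] <- adj
    t
  })
}

#' Principal component scores of an autoscaled table
#'
#' SVD-based PCA over samples, a diagnostic for batch structure (cohorts
#' separating on PC1 before batch adjustment and mixing after it). The sign
#' convention fixes each component so its largest-magnitude loading is
#' positive.
#'
#' @param table an autoscaled [feature_table()].
#' @param n_components number of components to return.
#' @return samples x components score matrix with attributes
#'   `"variance_fraction"` (per component) and `"loadings"`.
#' @export
pca_scores <- function(table, n_components = 2) {
  stopifnot(inherits(table, "feature_table"))
  if (table$transform_state != "autoscaled") {
    stop("pca_scores expects an autoscaled table", call. = FALSE)
  }
  x <- table$abundances
  if (n_components > min(dim(x))) {
    stop("n_components exceeds min(n_samples, n_features)", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  attr(scores, "variance_fraction") <- varfrac[seq_len(k)]
  attr(scores, "loadings") <- load
  scores
}
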