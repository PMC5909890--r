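#' Hanley-McNeil standard error of an AUC
#'
#' Closed-form SE of a ROC AUC from the two group sizes:
#' \deqn{SE = \sqrt{\frac{A(1-A) + (n_A-1)(Q_1-A^2) + (n_N-1)(Q_2-A^2)}
#'                       {n_A n_N}}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}, where \eqn{n_A} is
#' the number of cases (abnormals) and \eqn{n_N} the number of controls.
#'
#' @param A the AUC, in \[0, 1\].
#' @param n_cases,n_controls group sizes (>= 1).
#' @return the standard error (0 when `A` is exactly 1).
#' @examples
#' hanley_mcneil_se(0.791, 27, 36) # 0.0597
#' @export
hanley_mcneil_se <- function(A, n_cases, n_controls) {
  stopifnot(A >= 0, A <= 1)
  if (n_cases < 1 || n_controls < 1) {
    stop("group sizes must be at least 1", call. = FALSE)
  }
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n_cases - 1) * (q1 - A^2) +
          (n_controls - 1) * (q2 - A^2)) / (n_cases * n_controls)
  sqrt(max(v, 0))
}

#' Hanley-McNeil comparison of two independent ROC AUCs
#'
#' Two-tailed z-test of the null hypothesis that two AUCs estimated from
#' independent samples are equal:
#' \eqn{z = (A_1 - A_2)/\sqrt{SE_1^2 + SE_2^2}} with Hanley-McNeil standard
#' errors, \eqn{p = 2(1 - \Phi(|z|))}.
#'
#' @param roc1,roc2 `roc_result` objects (or lists carrying `auc`,
#'   `n_cases`, `n_controls`), e.g. from [roc_curve_auc()] or
#'   [roc_result()].
#' @param alpha significance level for the accept/reject conclusion.
#' @return a `roc_comparison`: list with `auc1`, `auc2`, `se1`, `se2`, `z`,
#'   `p`, and `conclusion` (`"reject_H0"` / `"accept_H0"`).
#' @examples
#' compare_independent_rocs(roc_result(0.791, 27, 36),
#'                          roc_result(0.738, 31, 53)) # z = 0.633, p = 0.527
#' @export
compare_independent_rocs <- function(roc1, roc2, alpha = 0.05) {
  need <- function(r) {
    stopifnot(all(c("auc", "n_cases", "n_controls") %in% names(r)))
    r
  }
  roc1 <- need(roc1)
  roc2 <- need(roc2)
  se1 <- hanley_mcneil_se(roc1$auc, roc1$n_cases, roc1$n_controls)
  se2 <- hanley_mcneil_se(roc2$auc, roc2$n_cases, roc2$n_controls)
  denom <- sqrt(se1^2 + se2^2)
  z <- if (denom == 0) {
    if (roc1$auc == roc2$auc) 0 else sign(roc1$auc - roc2$auc) * Inf
  } else {
    (roc1$auc - roc2$auc) / denom
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(auc1 = roc1$auc, auc2 = roc2$auc, se1 = se1, se2 = se2,
         z = z, p = p,
         conclusion = if (p < alpha) "reject_H0" else "accept_H0"),
    class = "roc_comparison")
}

#' @method print roc_comparison
#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf(
    "<roc_comparison> AUC %.3f vs %.3f: z = %.3f, p = %.3f -> %s\n",
    x$auc1, x$auc2, x$z, x$p, x$conclusion))
  invisible(x)
}

#' Chi-square goodness-of-fit test
#'
#' Pearson statistic \eqn{\sum (O-E)^2/E} of observed counts against
#' expected proportions, `df = cells - 1`.
#'
#' @param counts non-negative observed counts.
#' @param proportions expected fractions, summing to 1 (default uniform).
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' chisq_gof(c(26, 5))  # 14.23: the external-cohort TBI sex ratio
#' @export
chisq_gof <- function(counts, proportions = rep(1 / length(counts),
                                                length(counts))) {
  stopifnot(all(counts >= 0), length(counts) == length(proportions))
  if (abs(sum(proportions) - 1) > 1e-8) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  if (any(proportions <= 0)) {
    stop("expected counts must be positive", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, p = proportions))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Chi-square test of a 2x2 contingency table
#'
#' Pearson statistic, without continuity correction by default (the
#' convention that reproduces hand-calculator results); Yates correction by
#' flag.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `df` (= 1), `p`.
#' @examples
#' chisq_2x2(matrix(c(22, 26, 16, 5), 2)) # 5.44: mTBI sex ratio by cohort
#' @export
chisq_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("2x2 table has a zero margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Two-sample t-test
#'
#' Independent two-sample t-test, Welch (unequal variances) by default.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param welch use the Welch degrees-of-freedom correction.
#' @return list with `statistic`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, welch = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = length(x) + length(y) - 2, p = 1))
    }
    stop("both samples have zero variance", call. = FALSE)
  }
  res <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
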