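#' Logistic classification scores for HC vs SCI
#'
#' Maximum-likelihood logistic regression of group membership on a
#' predictor set, returning the in-sample (apparent) predicted
#' probabilities.  Under complete separation the scores from the
#' terminal IRLS iterate are still returned (with the usual warning).
#'
#' @param data Data frame with a `group` column (`"HC"`/`"SCI"`) and
#'   the predictor columns; rows with missing predictors are dropped.
#' @param predictors Character vector of predictor column names.
#' @return A list of class `ddk_logistic` with `scores` (fitted
#'   probabilities of SCI), `labels` (0 = HC, 1 = SCI), `ids`
#'   (row indices of `data` used), and `fit` coefficients.
#' @export
fit_logistic <- function(data, predictors) {
  stopifnot("group" %in% names(data),
            all(predictors %in% names(data)))
  keep <- stats::complete.cases(data[, predictors, drop = FALSE]) &
    !is.na(data$group)
  d <- data[keep, , drop = FALSE]
  y <- as.integer(d$group == "SCI")
  if (length(unique(y)) < 2)
    stop("both groups must be present")
  X <- stats::model.matrix(stats::reformulate(predictors), data = d)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  structure(list(scores = fit$fitted.values, labels = y,
                 ids = which(keep),
                 coefficients = fit$coefficients,
                 converged = fit$converged),
            class = "ddk_logistic")
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' AUC computed as the Mann-Whitney concordance probability with half
#' credit for ties, plus the ROC curve points.
#'
#' @param scores Numeric classification scores (higher = more likely
#'   positive).
#' @param labels 0/1 (or logical) class labels.
#' @return A list of class `ddk_roc` with `auc`, and curve points
#'   `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  m <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (m == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t),
                numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t),
                numeric(1))
  structure(list(auc = auc, fpr = fpr, tpr = tpr), class = "ddk_roc")
}

#' @export
print.ddk_roc <- function(x, ...) {
  cat(sprintf("<ddk_roc> AUC = %.4f (%d curve points)\n",
              x$auc, length(x$fpr)))
  invisible(x)
}

#' Paired comparison of two correlated ROC curves
#'
#' Compares the AUCs of two classifiers scored on the *same*
#' participants using the paired placement-value (DeLong) variance
#' estimate: for each case the placement value is its mean
#' concordance over all controls (and vice versa); the variance of
#' the AUC difference combines the placement-value covariance
#' matrices of cases and controls, and the two-sided p-value comes
#' from the normal reference distribution.
#'
#' @param scores_null,scores_full Score vectors from the two models,
#'   aligned to the same participants.
#' @param labels 0/1 class labels (1 = case).
#' @return A list of class `ddk_roc_comparison` with `auc_null`,
#'   `auc_full`, `statistic` (z), `p_value`, `n_cases`, `n_controls`.
#' @export
delong_compare <- function(scores_null, scores_full, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_null) == length(labels),
            length(scores_full) == length(labels))
  cases <- which(labels == 1)
  ctrls <- which(labels == 0)
  m <- length(cases)
  n0 <- length(ctrls)
  if (m == 0 || n0 == 0) stop("both classes must be present")

  placement <- function(s) {
    xs <- s[cases]; ys <- s[ctrls]
    # psi(x, y): 1 if x > y, 0.5 if tied, 0 otherwise
    v10 <- vapply(xs, function(x)
      mean((x > ys) + 0.5 * (x == ys)), numeric(1))
    v01 <- vapply(ys, function(y)
      mean((xs > y) + 0.5 * (xs == y)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  a <- placement(scores_null)
  b <- placement(scores_full)

  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- b$auc - a$auc
  if (var_diff <= 1e-16) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_null = a$auc, auc_full = b$auc,
                 statistic = z, p_value = p,
                 n_cases = m, n_controls = n0),
            class = "ddk_roc_comparison")
}

#' @export
print.ddk_roc_comparison <- function(x, ...) {
  cat(sprintf(
    "<ddk_roc_comparison> AUC null %.4f vs full %.4f (%d cases/%d controls)\n",
    x$auc_null, x$auc_full, x$n_cases, x$n_controls))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$statistic,
              x$p_value))
  invisible(x)
}
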