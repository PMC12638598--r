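#' Exhaustive AICc subset selection for count GLMs
#'
#' Evaluates the null model (the fixed covariate block alone) and
#' every subset of the candidate motor-speech features that contains
#' no forbidden pair, fitting each as a count GLM (Poisson or
#' negative binomial, log link) on one fixed complete-case set, and
#' ranks all models by AICc.  No interaction terms are considered.
#'
#' The complete-case set is computed once across the outcome, the
#' null covariates and *all* candidate features, and reused for every
#' subset, so AICc values are computed on identical data and are
#' comparable.  A model is deemed a significant improvement when
#' `delta_aicc = AICc_null - AICc_best` strictly exceeds 2.  The
#' candidate set comprises the models that improve on the null by
#' more than 2 AICc units *and* lie within 2 AICc units of the best
#' model; feature appearance rates are the fraction of candidate-set
#' models containing each feature.  Nagelkerke pseudo-R2 values are
#' reported against the intercept-only reference fit.
#'
#' @param data Data frame holding the outcome, null covariates and
#'   feature columns (e.g. one test/group slice of a `ddk_cohort`).
#' @param outcome Name of the count outcome column.
#' @param null_covariates Character vector of covariate column names
#'   always included (default: the demographic/clinical block).
#' @param features Character vector of candidate feature columns.
#' @param forbidden A `ddk_forbidden_pairs` object (or two-column
#'   matrix of feature names), or `NULL` for no constraint.
#' @param family `"poisson"` or `"nbinom"`.
#' @param cap Maximum number of candidate features for the
#'   exhaustive stage (default 10, i.e. at most `2^10` fits).
#' @return An object of class `ddk_selection`.
#' @export
exhaustive_selection <- function(data, outcome,
                                 null_covariates = c("age", "sex",
                                   "education", "psychiatric",
                                   "hads_anxiety", "hads_depression"),
                                 features,
                                 forbidden = NULL,
                                 family = c("poisson", "nbinom"),
                                 cap = 10) {
  family <- match.arg(family)
  features <- sort(unique(features))
  if (length(features) > cap)
    stop("number of candidate features (", length(features),
         ") exceeds cap (", cap, "); raise `cap` explicitly")
  stopifnot(all(c(outcome, null_covariates, features) %in% names(data)))

  keep <- stats::complete.cases(
    data[, c(outcome, null_covariates, features), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  y <- d[[outcome]]
  X_null <- stats::model.matrix(
    stats::reformulate(null_covariates), data = d)
  X_feat <- as.matrix(d[, features, drop = FALSE])

  # enumerate subsets containing no forbidden pair
  forb <- if (is.null(forbidden)) {
    matrix(character(), 0, 2)
  } else unclass(forbidden)
  subsets <- .enumerate_subsets(features, forb)

  fit_one <- function(X) {
    tryCatch(fit_count_glm(y, X, family = family),
             error = function(e) NULL)
  }
  intercept_fit <- fit_one(X_null[, 1, drop = FALSE])
  null_fit <- fit_one(X_null)
  if (is.null(null_fit) || is.null(intercept_fit))
    stop("null model failed to fit")

  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    X <- if (length(s)) cbind(X_null, X_feat[, s, drop = FALSE])
         else X_null
    fits[i] <- list(fit_one(X))   # keep NULLs as list slots
  }
  ok <- vapply(fits, function(f)
    !is.null(f) && is.finite(f$aicc), logical(1))
  n_failed <- sum(!ok)
  if (n_failed)
    warning(n_failed, " subset fits failed to converge and were ",
            "excluded from the ranking")
  if (!any(ok)) {
    warning("all feature models failed; reporting null model as best")
    ok[1] <- TRUE               # subset 1 is the empty (null) subset
  }

  ranking <- data.frame(
    subset = vapply(subsets[ok], paste, character(1), collapse = ","),
    n_features = lengths(subsets[ok]),
    k = vapply(fits[ok], `[[`, numeric(1), "k"),
    log_likelihood = vapply(fits[ok], `[[`, numeric(1),
                            "log_likelihood"),
    aicc = vapply(fits[ok], `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE)
  ord <- order(ranking$aicc, ranking$n_features, ranking$subset)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  ranking$delta <- ranking$aicc - ranking$aicc[1]

  best_idx <- which(ok)[ord][1]
  best_fit <- fits[[best_idx]]
  best_subset <- subsets[[best_idx]]
  delta_aicc <- null_fit$aicc - best_fit$aicc
  significant <- delta_aicc > 2

  improvement <- null_fit$aicc - ranking$aicc    # vs null, per model
  in_candidate <- improvement > 2 & ranking$delta < 2
  candidate_set <- ranking$subset[in_candidate]
  rates <- stats::setNames(numeric(length(features)), features)
  if (significant && length(candidate_set)) {
    members <- strsplit(candidate_set, ",", fixed = TRUE)
    for (f in features)
      rates[f] <- mean(vapply(members, function(m) f %in% m,
                              logical(1)))
  }

  r2n_null <- nagelkerke_r2(null_fit, intercept_fit)
  r2n_best <- nagelkerke_r2(best_fit, intercept_fit)

  structure(list(
    outcome = outcome, family = family, features = features,
    n = null_fit$n, n_models = sum(ok) ,
    n_failed = n_failed,
    subsets = subsets,
    ranking = ranking,
    null_fit = null_fit, best_fit = best_fit,
    best_subset = best_subset,
    delta_aicc = delta_aicc, significant = significant,
    r2n_null = r2n_null, r2n_best = r2n_best,
    delta_r2n = r2n_best - r2n_null,
    candidate_set = if (significant) candidate_set else character(),
    appearance_rates = if (significant) rates
                       else stats::setNames(numeric(0), character(0))),
    class = "ddk_selection")
}

.enumerate_subsets <- function(features, forbidden) {
  p <- length(features)
  subsets <- list(character(0))
  if (!p) return(subsets)
  for (size in seq_len(p)) {
    cmb <- utils::combn(features, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  if (nrow(forbidden)) {
    bad <- vapply(subsets, function(s) {
      any(forbidden[, 1] %in% s & forbidden[, 2] %in% s)
    }, logical(1))
    subsets <- subsets[!bad]
  }
  subsets
}

#' @export
print.ddk_selection <- function(x, ...) {
  cat(sprintf("<ddk_selection> outcome %s (%s), n = %d, %d models\n",
              x$outcome, x$family, x$n, x$n_models))
  cat(sprintf("  delta AICc (null - best) = %.2f%s\n", x$delta_aicc,
              if (x$significant) "  *significant (> 2)*" else ""))
  cat(sprintf("  R2_N null %.1f%%, best %.1f%% (delta %.1f%%)\n",
              x$r2n_null, x$r2n_best, x$delta_r2n))
  bs <- if (length(x$best_subset))
    paste(x$best_subset, collapse = ", ") else "(null model)"
  cat("  best subset:", bs, "\n")
  invisible(x)
}

#' @export
summary.ddk_selection <- function(object, n_show = 10, ...) {
  print(object)
  cat(sprintf("\nTop models (of %d evaluated; %d failed):\n",
              object$n_models, object$n_failed))
  print(utils::head(object$ranking, n_show), digits = 6)
  if (object$significant) {
    cat(sprintf("\nCandidate set (%d models within 2 AICc of best):\n",
                length(object$candidate_set)))
    ar <- sort(object$appearance_rates, decreasing = TRUE)
    ar <- ar[ar > 0]
    for (f in names(ar))
      cat(sprintf("  %-24s %5.1f%%\n", f, 100 * ar[f]))
  }
  invisible(object)
}

#' @export
coef.ddk_selection <- function(object, ...) coef(object$best_fit)

#' Feature appearance rates in the candidate model set
#'
#' For a significant selection result, the fraction of candidate-set
#' models (those improving on the null by more than 2 AICc units and
#' within 2 units of the best model) that contain each feature.  A
#' rate of 1 means the feature appeared in every candidate model.
#'
#' @param result A `ddk_selection`.
#' @return Named numeric vector over the candidate features; empty
#'   when the result is not significant.
#' @export
appearance_rates <- function(result) {
  stopifnot(inherits(result, "ddk_selection"))
  result$appearance_rates
}
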