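#' Small-sample corrected Akaike information criterion
#'
#' `AIC = 2k - 2 logL`; `AICc = AIC + 2k(k+1)/(n - k - 1)`.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Number of estimated parameters (intercept, slopes, and the
#'   negative-binomial dispersion where applicable).
#' @param n Number of observations.
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  2 * k - 2 * log_likelihood + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a count GLM (Poisson or negative binomial) with a log link
#'
#' Maximum-likelihood fit of a count outcome on a design matrix.
#' Negative-binomial dispersion (the size parameter `theta`) is
#' estimated jointly by alternating weighted-least-squares steps
#' (`glm.fit` with the [MASS::negative.binomial] family) with
#' [MASS::theta.ml] updates until the log-likelihood stabilizes —
#' the same alternation `MASS::glm.nb` performs, run on a prebuilt
#' model matrix so that thousands of subset fits stay fast.
#'
#' @param y Non-negative integer outcome vector.
#' @param X Design matrix including an intercept column.
#' @param family `"poisson"` or `"nbinom"`.
#' @param max_iter,tol Convergence controls for the NB alternation
#'   (relative log-likelihood change).
#' @return An object of class `ddk_glm`: coefficients, `theta` (NB
#'   size, `NA` for Poisson), `log_likelihood`, `k` (parameter count,
#'   including `theta` for NB), `n`, `aic`, `aicc`, `fitted`,
#'   `converged`, `family`.
#' @export
fit_count_glm <- function(y, X, family = c("poisson", "nbinom"),
                          max_iter = 50, tol = 1e-10) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(y >= 0), all(y == round(y)))
  if (n < ncol(X) + 2)
    stop("too few complete cases: need at least k + 2")

  if (family == "poisson") {
    fit <- stats::glm.fit(X, y, family = stats::poisson())
    mu <- fit$fitted.values
    ll <- sum(stats::dpois(y, mu, log = TRUE))
    k <- ncol(X)
    theta <- NA_real_
    converged <- fit$converged
    coefs <- fit$coefficients
  } else {
    # moment initializer for theta, guarded away from degeneracy
    mu0 <- pmax(mean(y), 1e-3)
    v <- stats::var(y)
    theta <- if (v > mu0) mu0^2 / (v - mu0) else 100
    theta <- min(max(theta, 0.05), 1e4)
    ll_old <- -Inf
    converged <- FALSE
    coefs <- NULL
    mu <- rep(mu0, n)
    for (it in seq_len(max_iter)) {
      fam <- MASS::negative.binomial(theta)
      fit <- suppressWarnings(
        stats::glm.fit(X, y, family = fam,
                       control = stats::glm.control(maxit = 50)))
      mu <- fit$fitted.values
      th_new <- tryCatch(
        suppressWarnings(as.numeric(
          MASS::theta.ml(y, mu, limit = 50, trace = FALSE))),
        error = function(e) NA_real_)
      # equidispersed data drives theta towards infinity; cap it so
      # the working family stays numerically valid
      if (is.finite(th_new)) theta <- min(th_new, 1e6)
      ll <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
      coefs <- fit$coefficients
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    k <- ncol(X) + 1L      # theta counted as an estimated parameter
  }
  structure(list(coefficients = coefs, theta = theta,
                 log_likelihood = ll, k = k, n = n,
                 aic = 2 * k - 2 * ll, aicc = aicc(ll, k, n),
                 fitted = mu, family = family,
                 converged = isTRUE(converged)),
            class = "ddk_glm")
}

#' @export
print.ddk_glm <- function(x, digits = 4, ...) {
  cat(sprintf("<ddk_glm> %s (log link), n = %d, k = %d\n",
              x$family, x$n, x$k))
  cat(sprintf("  logLik %.4f, AICc %.4f%s\n", x$log_likelihood, x$aicc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, digits))
  if (x$family == "nbinom")
    cat(sprintf("  theta (NB size): %.4f\n", x$theta))
  invisible(x)
}

#' @export
coef.ddk_glm <- function(object, ...) object$coefficients

#' @export
logLik.ddk_glm <- function(object, ...) {
  structure(object$log_likelihood, df = object$k,
            nobs = object$n, class = "logLik")
}

#' @export
predict.ddk_glm <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    return(log(object$fitted))
  }
  eta <- as.numeric(as.matrix(newdata) %*% object$coefficients)
  if (type == "response") exp(eta) else eta
}

#' Nagelkerke pseudo-R-squared (percent)
#'
#' `R2_CS = 1 - exp((2/n)(logL0 - logL1))`, rescaled by its maximum
#' `1 - exp((2/n) logL0)` and returned as a percentage.  The
#' reference fit is typically the intercept-only model.
#'
#' @param fit,null_fit `ddk_glm` fits of the same outcome on the same
#'   cases (`null_fit` is the reference, e.g. intercept-only).
#' @return R2_N in percent.
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  stopifnot(fit$n == null_fit$n)
  n <- fit$n
  ll1 <- fit$log_likelihood
  ll0 <- null_fit$log_likelihood
  if (ll1 < ll0 - 1e-8)
    warning("reference model has higher likelihood than fit; ",
            "R2_N will be negative")
  r2_cs <- 1 - exp((2 / n) * (ll0 - ll1))
  r2_max <- 1 - exp((2 / n) * ll0)
  100 * r2_cs / r2_max
}
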