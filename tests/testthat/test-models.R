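test_that("AICc follows its closed form and penalty properties", {
  # hand-evaluated case: logL = -4.326, k = 1, n = 3
  expect_equal(aicc(-4.326, 1, 3), 10.652 + 4, tolerance = 1e-9)
  # converges to AIC for large n
  expect_lt(abs(aicc(-100, 3, 1e9) - (2 * 3 + 200)), 1e-6)
  # equal likelihood, one extra parameter: strictly worse
  expect_gt(aicc(-50, 4, 100), aicc(-50, 3, 100))
  # undefined below the sample-size floor
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("the intercept-only Poisson MLE is the sample mean", {
  fit <- fit_count_glm(c(1L, 2L, 3L), matrix(1, 3, 1), "poisson")
  expect_equal(unname(exp(fit$coefficients[1])), 2, tolerance = 1e-9)
})

test_that("count GLM fits match the reference implementations", {
  set.seed(20)
  n <- 400
  x <- stats::rnorm(n)
  d <- data.frame(x = x,
                  y_po = stats::rpois(n, exp(1 + 0.3 * x)),
                  y_nb = stats::rnbinom(n, size = 1.5,
                                        mu = exp(1 + 0.3 * x)))
  X <- cbind(1, x)

  fit_po <- fit_count_glm(d$y_po, X, "poisson")
  ref_po <- stats::glm(y_po ~ x, stats::poisson, d)
  expect_equal(unname(fit_po$coefficients), unname(coef(ref_po)),
               tolerance = 1e-8)
  expect_equal(fit_po$log_likelihood, as.numeric(logLik(ref_po)),
               tolerance = 1e-8)
  expect_equal(fit_po$k, 2)

  fit_nb <- fit_count_glm(d$y_nb, X, "nbinom")
  ref_nb <- MASS::glm.nb(y_nb ~ x, d)
  expect_equal(unname(fit_nb$coefficients), unname(coef(ref_nb)),
               tolerance = 1e-4)
  expect_equal(fit_nb$log_likelihood, as.numeric(logLik(ref_nb)),
               tolerance = 1e-6)
  expect_equal(fit_nb$theta, ref_nb$theta, tolerance = 1e-4)
  expect_equal(fit_nb$k, 3)                # slope, intercept, theta
  expect_gte(fit_nb$aicc, fit_nb$aic)
})

test_that("simulated slopes are recovered without bias", {
  set.seed(21)
  n <- 2000
  x <- stats::rnorm(n)
  y <- stats::rpois(n, exp(0.8 + 0.3 * x))
  fit <- fit_count_glm(y, cbind(1, x), "poisson")
  expect_lt(abs(fit$coefficients[2] - 0.3), 0.05)

  # NB fit on Poisson data: dispersion estimate drifts large
  fit_nb <- fit_count_glm(y, cbind(1, x), "nbinom")
  expect_gt(fit_nb$theta, 50)
})

test_that("Nagelkerke R2 is zero at no improvement and 100 at saturation", {
  f <- structure(list(log_likelihood = -40, n = 20), class = "ddk_glm")
  expect_equal(nagelkerke_r2(f, f), 0)
  # a perfectly saturated discrete fit reaches the normalised maximum
  sat <- structure(list(log_likelihood = 0, n = 20), class = "ddk_glm")
  ref <- structure(list(log_likelihood = -13.46, n = 20),
                   class = "ddk_glm")
  expect_equal(nagelkerke_r2(sat, ref), 100)
})

test_that("Nagelkerke R2 matches an independent computation", {
  d <- sim_analysis_frame(300, seed = 22)
  X <- stats::model.matrix(stats::reformulate(null_covs), d)
  y <- d$executive_strategy
  i0 <- fit_count_glm(y, X[, 1, drop = FALSE], "poisson")
  f1 <- fit_count_glm(y, X, "poisson")
  ll0 <- as.numeric(logLik(stats::glm(y ~ 1, stats::poisson)))
  ll1 <- as.numeric(logLik(stats::glm(
    stats::reformulate(null_covs, "executive_strategy"),
    stats::poisson, d)))
  n <- length(y)
  ref <- 100 * (1 - exp(2 / n * (ll0 - ll1))) /
    (1 - exp(2 / n * ll0))
  expect_equal(nagelkerke_r2(f1, i0), ref, tolerance = 1e-8)
})

test_that("subset enumeration respects the forbidden-pair constraint", {
  forb <- structure(rbind(c("A", "B")), class = "ddk_forbidden_pairs")
  subs <- ddktools:::.enumerate_subsets(c("A", "B", "C"),
                                        unclass(forb))
  canon <- lapply(subs, sort)
  expect_length(canon, 6)
  expect_true(list(character(0)) %in% list(canon[[1]]))
  for (want in list("A", "B", "C", c("A", "C"), c("B", "C")))
    expect_true(any(vapply(canon, identical, logical(1), want)))
  for (s in canon)
    expect_false(all(c("A", "B") %in% s))
})

test_that("exhaustive selection ranks identically for any feature order
           and never loses the nested-likelihood ordering", {
  d <- sim_analysis_frame(250, seed = 23,
    feature_effects = list(executive_strategy = c(ioi_sd = 0.25)))
  feats <- c("ioi_sd", "vot_mean", "pause_cov")
  sel <- exhaustive_selection(d, "executive_strategy",
                              features = feats, family = "poisson")
  sel_rev <- exhaustive_selection(d, "executive_strategy",
                                  features = rev(feats),
                                  family = "poisson")
  expect_equal(sel$ranking, sel_rev$ranking)
  expect_equal(sel$delta_aicc, sel_rev$delta_aicc)

  # adding a feature never lowers the ML log-likelihood
  r <- sel$ranking
  ll_null <- sel$null_fit$log_likelihood
  for (i in seq_len(nrow(r)))
    if (r$n_features[i] > 0)
      expect_gte(r$log_likelihood[i], ll_null - 1e-6)

  # planted feature rises to the top
  expect_true(sel$significant)
  expect_true("ioi_sd" %in% sel$best_subset)
  ar <- appearance_rates(sel)
  expect_equal(unname(ar["ioi_sd"]), 1)
  expect_true(all(ar >= 0 & ar <= 1))
})

test_that("candidate sets exist exactly when the result is significant", {
  d_null <- sim_analysis_frame(250, seed = 24)
  sel <- exhaustive_selection(d_null, "executive_strategy",
                              features = c("vot_mean", "pause_cov"),
                              family = "poisson")
  expect_identical(sel$significant, sel$delta_aicc > 2)
  if (!sel$significant) {
    expect_length(sel$candidate_set, 0)
    expect_length(appearance_rates(sel), 0)
  }
  d_eff <- sim_analysis_frame(800, seed = 25,
    feature_effects = list(executive_strategy = c(ioi_sd = 0.3)))
  sel2 <- exhaustive_selection(d_eff, "executive_strategy",
                               features = c("ioi_sd", "vot_mean"),
                               family = "poisson")
  expect_true(sel2$significant)
  expect_gt(length(sel2$candidate_set), 0)
})

test_that("selection refuses feature sets beyond the cap", {
  d <- sim_analysis_frame(100, seed = 26)
  expect_error(
    exhaustive_selection(d, "executive_strategy",
                         features = ddk_feature_names(),
                         family = "poisson", cap = 10),
    "cap")
})

test_that("Wald coverage and bias stay nominal across the grid", {
  # moderate-scale parameter recovery for the Poisson slope
  set.seed(27)
  est <- se <- numeric(60)
  for (r in 1:60) {
    n <- 2000
    x <- stats::rnorm(n)
    y <- stats::rpois(n, exp(0.8 + 0.3 * x))
    fit <- stats::glm.fit(cbind(1, x), y, family = stats::poisson())
    est[r] <- fit$coefficients[2]
    # Wald SE from the Fisher information
    W <- fit$weights
    info <- crossprod(cbind(1, x) * sqrt(W))
    se[r] <- sqrt(solve(info)[2, 2])
  }
  expect_lt(abs(mean(est) - 0.3), 0.02)
  cover <- mean(abs(est - 0.3) <= 1.96 * se)
  expect_gte(cover, 0.90)
  expect_lte(cover, 1.00)
})
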