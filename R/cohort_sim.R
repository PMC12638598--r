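#' Specification of a simulated DDK study cohort
#'
#' Defines the generative model for a synthetic cohort of older
#' adults with per-participant motor-speech parameters, demographic
#' and clinical covariates, and count-valued cognitive outcomes drawn
#' from Poisson / negative-binomial GLMs with known coefficients.
#'
#' Covariate distributions follow the demographic summaries typical
#' of a community sample aged 50+: age ~ Normal(66.9, 7.3) truncated
#' at 50; sex female with probability 0.72; education a 5-level
#' ordinal (high school ... higher degree) with probabilities
#' (0.098, 0.069, 0.202, 0.230, 0.401); a psychiatric-diagnosis flag
#' (probability 0.15 HC / 0.30 SCI); HADS anxiety and depression as
#' overdispersed small counts capped at 21 (means ~5 and ~2.5 in HC,
#' higher in SCI).
#'
#' The executive-function outcome is Poisson; the episodic-memory and
#' working-memory outcomes are negative binomial with size
#' `nb_dispersion` (overdispersion).  The linear predictor is
#' `intercept + null covariate block + planted feature effects`,
#' where `feature_effects` are per-SD effects applied to the
#' standardized latent features.
#'
#' @param n_participants Cohort size.
#' @param group_fraction_sci Proportion assigned to the SCI group.
#' @param null_coefficients Named coefficients of the covariate block
#'   (applied on the log-link scale; continuous covariates centred).
#' @param intercepts Named per-outcome intercepts (log scale).
#' @param feature_effects Named list per outcome
#'   (`episodic_memory`, `executive_strategy`, `working_memory`) of
#'   named per-SD feature effects; empty = null world.
#' @param group_feature_shift Named per-SD shifts added to the
#'   features of SCI participants (for classification simulations);
#'   empty = no group difference.
#' @param nb_dispersion Negative-binomial size parameter (> 0).
#' @param missing_recording_rate Per-(participant, test) probability
#'   that a recording is missing/unusable.
#' @param test_jitter_sd Log-scale SD of the per-test jitter applied
#'   to participant-level speech parameters.
#' @param duration DDK recording length, seconds.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 200,
                        group_fraction_sci = 0.17,
                        null_coefficients = c(age = 0.010,
                                              sexM = -0.10,
                                              education = -0.05,
                                              psychiatric = 0.10,
                                              hads_anxiety = 0.015,
                                              hads_depression = 0.025),
                        intercepts = c(episodic_memory = log(4.1),
                                       executive_strategy = log(7.7),
                                       working_memory = log(3.2)),
                        feature_effects = list(),
                        group_feature_shift = numeric(),
                        nb_dispersion = 1.2,
                        missing_recording_rate = 0.07,
                        test_jitter_sd = 0.03,
                        duration = 10,
                        seed = 1L) {
  stopifnot(group_fraction_sci >= 0, group_fraction_sci <= 1,
            missing_recording_rate >= 0, missing_recording_rate <= 1,
            nb_dispersion > 0)
  bad <- names(null_coefficients)[!is.finite(null_coefficients)]
  if (length(bad))
    stop("non-finite null coefficient: ", bad[1])
  for (o in names(feature_effects)) {
    fe <- feature_effects[[o]]
    if (length(fe) && any(!is.finite(fe)))
      stop("non-finite feature effect: ",
           names(fe)[!is.finite(fe)][1], " (outcome ", o, ")")
    if (!all(names(fe) %in% ddk_feature_names()))
      stop("unknown feature in feature_effects: ",
           setdiff(names(fe), ddk_feature_names())[1])
  }
  structure(list(n_participants = as.integer(n_participants),
                 group_fraction_sci = group_fraction_sci,
                 null_coefficients = null_coefficients,
                 intercepts = intercepts,
                 feature_effects = feature_effects,
                 group_feature_shift = group_feature_shift,
                 nb_dispersion = nb_dispersion,
                 missing_recording_rate = missing_recording_rate,
                 test_jitter_sd = test_jitter_sd,
                 duration = duration,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# overdispersed small-count score capped at `cap`
.rhads <- function(n, mean, sd, cap = 21) {
  v <- sd^2
  x <- if (v > mean) {
    stats::rnbinom(n, size = mean^2 / (v - mean), mu = mean)
  } else stats::rpois(n, mean)
  pmin(x, cap)
}

#' Simulate a DDK study cohort with known ground truth
#'
#' Draws per-participant speech parameters (syllable rate, IOI
#' jitter and drift, syllable duration, VOT, SNR, f0), derives the
#' 19 latent motor-speech features from them in closed form, samples
#' covariates, and generates the three count outcomes from the
#' specified GLMs.  Per-test "true" features are the latent features
#' under small per-test jitter; a fraction of (participant, test)
#' recordings is marked missing.
#'
#' @param spec A [cohort_spec].
#' @return A list of class `ddk_cohort_sim` with elements:
#'   `cohort` (covariates + outcomes), `features` (per participant
#'   and test, jittered truth; missing recordings omitted),
#'   `params` (per participant and test, the synthesis parameters
#'   with a `missing` flag), `latent_features`, and `truth` (the
#'   generating coefficients, per-SD effects, standardization
#'   constants, and linear predictors).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  id <- sprintf("P%04d", seq_len(n))
  group <- ifelse(stats::runif(n) < spec$group_fraction_sci,
                  "SCI", "HC")

  age <- round(.rnorm_trunc(n, 66.9, 7.3, lo = 50))
  sex <- ifelse(stats::runif(n) < 0.72, "F", "M")
  education <- sample(1:5, n, replace = TRUE,
                      prob = c(0.098, 0.069, 0.202, 0.230, 0.401))
  p_psych <- ifelse(group == "SCI", 0.30, 0.15)
  psychiatric <- as.integer(stats::runif(n) < p_psych)
  hads_anxiety <- ifelse(group == "SCI",
                         .rhads(n, 6.5, 3.9), .rhads(n, 5.0, 3.4))
  hads_depression <- ifelse(group == "SCI",
                            .rhads(n, 4.7, 3.2), .rhads(n, 2.5, 2.2))

  # participant-level latent speech parameters
  rate <- .rnorm_trunc(n, 4.5, 0.7, 2.5, 6.5)          # syll/s
  ioi_mean <- 1 / rate
  ioi_sd <- pmax(stats::rnorm(n, 0.010, 0.004), 0.002)
  drift <- stats::rnorm(n, 0.05, 0.04)
  syl <- pmin(.rnorm_trunc(n, 0.12, 0.015, 0.07, 0.18),
              0.75 * ioi_mean)
  vot <- pmin(.rnorm_trunc(n, 0.040, 0.010, 0.015, 0.080),
              syl - 0.020)
  syl_cov <- pmax(stats::rnorm(n, 0.08, 0.03), 0.01)
  vot_cov <- pmax(stats::rnorm(n, 0.18, 0.05), 0.02)
  strength_cov <- pmax(stats::rnorm(n, 0.25, 0.08), 0.03)
  snr_db <- .rnorm_trunc(n, 25, 4, 18, 40)
  f0 <- .rnorm_trunc(n, 115, 20, 80, 220)

  latent <- .features_from_params(ioi_mean, ioi_sd, drift, syl, vot,
                                  syl_cov, vot_cov, strength_cov,
                                  spec$duration)

  # optional group-level feature shift (per SD, SCI participants)
  if (length(spec$group_feature_shift)) {
    for (f in names(spec$group_feature_shift)) {
      s <- stats::sd(latent[, f])
      latent[group == "SCI", f] <- latent[group == "SCI", f] +
        spec$group_feature_shift[[f]] * s
    }
  }

  # standardized latent features for effect planting
  z <- scale(latent)
  z[, apply(latent, 2, stats::sd) == 0] <- 0

  b <- spec$null_coefficients
  eta_null <- b[["age"]] * (age - 67) +
    b[["sexM"]] * (sex == "M") +
    b[["education"]] * (education - 3) +
    b[["psychiatric"]] * psychiatric +
    b[["hads_anxiety"]] * (hads_anxiety - 5) +
    b[["hads_depression"]] * (hads_depression - 3)

  outcomes <- list()
  eta_all <- list()
  for (o in c("episodic_memory", "executive_strategy",
              "working_memory")) {
    eta <- spec$intercepts[[o]] + eta_null
    fe <- spec$feature_effects[[o]]
    if (length(fe))
      for (f in names(fe)) eta <- eta + fe[[f]] * z[, f]
    if (any(!is.finite(eta))) {
      coefs <- c(b, if (length(fe)) fe)
      bad <- names(coefs)[!is.finite(coefs)]
      stop("non-finite linear predictor for ", o,
           if (length(bad)) paste0(" (offending coefficient: ",
                                   bad[1], ")"))
    }
    eta_all[[o]] <- eta
    outcomes[[o]] <- if (o == "executive_strategy") {
      stats::rpois(n, exp(eta))
    } else {
      stats::rnbinom(n, size = spec$nb_dispersion, mu = exp(eta))
    }
  }

  cohort <- data.frame(participant_id = id, group = group, age = age,
                       sex = sex, education = education,
                       psychiatric = psychiatric,
                       hads_anxiety = hads_anxiety,
                       hads_depression = hads_depression,
                       episodic_memory = outcomes$episodic_memory,
                       executive_strategy = outcomes$executive_strategy,
                       working_memory = outcomes$working_memory,
                       stringsAsFactors = FALSE)

  # per-test parameter jitter, true features, and missingness
  tests <- c("pa", "ta", "ka")
  params <- list(); feats <- list()
  for (t in tests) {
    j <- function(x) x * exp(stats::rnorm(n, 0, spec$test_jitter_sd))
    im <- j(ioi_mean); isd <- j(ioi_sd); sy <- pmin(j(syl), 0.75 * im)
    vo <- pmin(j(vot), sy - 0.015)
    ft <- .features_from_params(im, isd, drift, sy, vo,
                                j(syl_cov), j(vot_cov),
                                j(strength_cov), spec$duration)
    if (length(spec$group_feature_shift)) {
      for (f in names(spec$group_feature_shift)) {
        s <- stats::sd(ft[, f])
        ft[group == "SCI", f] <- ft[group == "SCI", f] +
          spec$group_feature_shift[[f]] * s
      }
    }
    missing <- stats::runif(n) < spec$missing_recording_rate
    params[[t]] <- data.frame(
      participant_id = id, test = t, ioi_mean = im, ioi_sd = isd,
      ioi_drift = drift, syllable_duration = sy, vot = vo,
      vowel_f0 = f0, snr_db = snr_db, missing = missing,
      stringsAsFactors = FALSE)
    fd <- data.frame(participant_id = id, test = t,
                     stringsAsFactors = FALSE)
    fd <- cbind(fd, as.data.frame(ft))
    feats[[t]] <- fd[!missing, , drop = FALSE]
  }

  structure(list(
    cohort = cohort,
    features = do.call(rbind, feats),
    params = do.call(rbind, params),
    latent_features = latent,
    truth = list(spec = spec,
                 eta = eta_all,
                 feature_mean = attr(z, "scaled:center"),
                 feature_sd = attr(z, "scaled:scale"))),
    class = "ddk_cohort_sim")
}

#' @export
print.ddk_cohort_sim <- function(x, ...) {
  cat(sprintf("<ddk_cohort_sim> %d participants (%d SCI), %d feature rows\n",
              nrow(x$cohort), sum(x$cohort$group == "SCI"),
              nrow(x$features)))
  invisible(x)
}

# closed-form 19-feature vector implied by the synthesis parameters
.features_from_params <- function(ioi_mean, ioi_sd, drift, syl, vot,
                                  syl_cov, vot_cov, strength_cov,
                                  duration, start = 0.5) {
  count <- floor((duration - start - syl) / ioi_mean) + 1
  n_ioi <- pmax(count - 1, 1)
  pause <- ioi_mean - syl
  # expected minimum of n_ioi jittered IOIs (first-order normal
  # extreme-value approximation), guarded away from zero
  exp_min <- pmax(ioi_mean * (1 - abs(drift) / 2) -
                    ioi_sd * sqrt(2 * log(pmax(n_ioi, 2))),
                  0.5 * ioi_mean)
  cbind(
    onset_count = count,
    onset_rate = count / duration,
    ioi_mean = ioi_mean,
    ioi_sd = ioi_sd,
    inverse_min_ioi = 1 / exp_min,
    decrement_on_ioi = log((1 + drift / 2) / (1 - drift / 2)) / n_ioi,
    inverse_ioi_mean = (1 / ioi_mean) * (1 + (ioi_sd / ioi_mean)^2),
    inverse_ioi_cov = ioi_sd / ioi_mean,
    articulation_rate = 1 / syl,
    syllable_duration_mean = syl,
    syllable_duration_cov = syl_cov,
    speech_percent = 100 * count * syl / duration,
    speech_to_pause_ratio = (count * syl) / (n_ioi * pause),
    pause_mean = pause,
    pause_cov = sqrt(ioi_sd^2 + (syl * syl_cov)^2) / pause,
    pause_percent = 100 * n_ioi * pause / duration,
    vot_mean = vot,
    vot_cov = vot_cov,
    onset_strength_cov = strength_cov)
}

#' Write the simulated cohort to CSV
#'
#' Writes the cohort covariate/outcome table and the per-test feature
#' table as two CSV files with documented headers (missing values as
#' empty fields).
#'
#' @param sim A `ddk_cohort_sim` from [simulate_cohort()].
#' @param cohort_path,features_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort_csv <- function(sim, cohort_path, features_path) {
  utils::write.csv(sim$cohort, cohort_path, row.names = FALSE, na = "")
  utils::write.csv(sim$features, features_path, row.names = FALSE,
                   na = "")
  invisible(c(cohort_path, features_path))
}
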