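#' Pipeline configuration
#'
#' Assembles the full configuration of an end-to-end run:
#' simulation, preprocessing, feature extraction, model selection and
#' classification parameters.  The configuration is a plain named
#' list and is written beside the outputs as a snapshot, so every
#' output row is traceable to the run that produced it.
#'
#' @param n_participants Cohort size.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for the report bundle.
#' @param use_audio Synthesize and analyse audio for every recording
#'   (`TRUE`), or analyse the simulated true features directly
#'   (`FALSE`, fast statistical-only run).
#' @param features Candidate features for the exhaustive stage.  The
#'   default 10-feature panel spans the six quality groups (onset,
#'   IOI, syllable, pause, voice onset, energy); pass
#'   `ddk_feature_names()` for the full 19 (raise `cap` accordingly).
#' @param cap Feature cap for the exhaustive stage (default 10).
#' @param correlation_threshold Forbidden-pair threshold.
#' @param denoise_audio Apply spectral gating before extraction.
#' @param synth_rate Sample rate of synthesized audio, Hz.
#' @param min_duration Screening minimum duration, s.
#' @param ... Passed to [cohort_spec()] (e.g. `feature_effects`,
#'   `missing_recording_rate`, `nb_dispersion`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 200, seed = 1L,
                            out_dir = tempfile("ddk_run_"),
                            use_audio = TRUE,
                            features = c("onset_count", "ioi_mean",
                              "ioi_sd", "inverse_min_ioi",
                              "decrement_on_ioi", "articulation_rate",
                              "syllable_duration_cov",
                              "speech_to_pause_ratio", "pause_mean",
                              "vot_mean"),
                            cap = 10,
                            correlation_threshold = 0.6,
                            denoise_audio = TRUE,
                            synth_rate = 16000,
                            min_duration = 2, ...) {
  structure(list(n_participants = n_participants,
                 seed = as.integer(seed), out_dir = out_dir,
                 use_audio = use_audio, features = features,
                 cap = cap,
                 correlation_threshold = correlation_threshold,
                 denoise_audio = denoise_audio,
                 synth_rate = synth_rate,
                 min_duration = min_duration,
                 cohort_args = list(...)),
            class = "pipeline_config")
}

#' Run the full DDK analysis pipeline
#'
#' Executes simulate -> screen/denoise -> extract -> assemble ->
#' select -> classify: simulates a cohort, synthesizes one recording
#' per participant and DDK test (unless `use_audio = FALSE`), screens
#' and denoises each recording and extracts the 19 features, builds
#' the analysis table and per-group forbidden-pair sets, runs all 18
#' group x outcome x test exhaustive selections, and the 3 per-test
#' paired ROC comparisons of null vs null + features classifiers.
#'
#' Outputs written to `config$out_dir`: `selection_report.csv` (18
#' rows), `appearance_rates.csv` (long format, significant runs),
#' `roc_report.csv` (3 rows), `exclusions.csv`, and
#' `config_snapshot.txt`.  Identical seeds give identical outputs.
#'
#' @param config A [pipeline_config].
#' @param progress Print per-stage progress lines to stderr.
#' @return Invisibly, a list of class `ddk_pipeline_result` with the
#'   report data frames, the selection objects, and the output paths.
#' @export
run_pipeline <- function(config, progress = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (progress) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[1/5] simulating cohort (n = %d)", config$n_participants)
  spec <- do.call(cohort_spec,
                  c(list(n_participants = config$n_participants,
                         seed = config$seed),
                    config$cohort_args))
  sim <- simulate_cohort(spec)

  exclusions <- sim$params[sim$params$missing,
                           c("participant_id", "test")]
  if (nrow(exclusions)) exclusions$reason <- "missing_recording"
  else exclusions$reason <- character(0)

  if (config$use_audio) {
    say("[2/5] synthesizing and analysing %d recordings",
        sum(!sim$params$missing))
    feat <- .extract_cohort_audio(sim, config)
    exclusions <- rbind(exclusions, feat$exclusions)
    features_df <- feat$features
  } else {
    say("[2/5] using simulated true features (no audio)")
    features_df <- sim$features
  }

  say("[3/5] assembling feature table and forbidden pairs")
  table <- build_feature_table(features_df, sim$cohort)
  forb <- list()
  pair_set <- function(group) forbidden_pairs(
    correlation_matrix(table, "pa", group),
    correlation_matrix(table, "ta", group),
    correlation_matrix(table, "ka", group),
    threshold = config$correlation_threshold)
  for (g in c("HC", "SCI")) {
    # a group too small for within-group correlations falls back to
    # the pooled matrices
    forb[[g]] <- tryCatch(pair_set(g), error = function(e) {
      warning("within-", g, " correlations unavailable (",
              conditionMessage(e), "); using pooled correlations")
      pair_set(NULL)
    })
  }

  say("[4/5] running 18 selection analyses")
  fam_of <- c(episodic_memory = "nbinom",
              executive_strategy = "poisson",
              working_memory = "nbinom")
  sel_rows <- list(); app_rows <- list(); selections <- list()
  for (g in c("HC", "SCI")) {
    for (o in names(fam_of)) {
      for (t in c("pa", "ta", "ka")) {
        d <- .analysis_frame(table, t, g)
        key <- paste(g, o, t, sep = ".")
        res <- tryCatch(
          suppressWarnings(exhaustive_selection(
            d, o, features = config$features,
            forbidden = forb[[g]], family = fam_of[[o]],
            cap = config$cap)),
          error = function(e) e)
        if (inherits(res, "error")) {
          warning("selection run ", key, " failed: ",
                  conditionMessage(res))
          sel_rows[[key]] <- data.frame(
            group = g, outcome = o, test = t, n = nrow(d),
            n_models = 0L, delta_aicc = NA_real_,
            significant = NA, r2n_null = NA_real_,
            r2n_best = NA_real_, delta_r2n = NA_real_,
            best_subset = NA_character_, stringsAsFactors = FALSE)
          next
        }
        selections[[key]] <- res
        sel_rows[[key]] <- data.frame(
          group = g, outcome = o, test = t, n = res$n,
          n_models = res$n_models,
          delta_aicc = round(res$delta_aicc, 4),
          significant = res$significant,
          r2n_null = round(res$r2n_null, 4),
          r2n_best = round(res$r2n_best, 4),
          delta_r2n = round(res$delta_r2n, 4),
          best_subset = paste(res$best_subset, collapse = ";"),
          stringsAsFactors = FALSE)
        if (res$significant) {
          ar <- appearance_rates(res)
          app_rows[[key]] <- data.frame(
            group = g, outcome = o, test = t,
            feature = names(ar), rate = round(as.numeric(ar), 4),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  selection_report <- do.call(rbind, sel_rows)
  rownames(selection_report) <- NULL
  appearance_report <- if (length(app_rows)) {
    a <- do.call(rbind, app_rows); rownames(a) <- NULL; a
  } else data.frame(group = character(), outcome = character(),
                    test = character(), feature = character(),
                    rate = numeric())

  say("[5/5] running 3 ROC comparisons")
  roc_rows <- list()
  null_covs <- c("age", "sex", "education", "psychiatric",
                 "hads_anxiety", "hads_depression")
  for (t in c("pa", "ta", "ka")) {
    d <- .analysis_frame(table, t)
    cmp <- compare_group_classifiers(d, null_covs, config$features)
    roc_rows[[t]] <- data.frame(
      test = t, auc_null = round(cmp$auc_null, 4),
      auc_full = round(cmp$auc_full, 4),
      statistic = round(cmp$statistic, 4),
      p_value = signif(cmp$p_value, 6),
      n_cases = cmp$n_cases, n_controls = cmp$n_controls,
      stringsAsFactors = FALSE)
  }
  roc_report <- do.call(rbind, roc_rows)
  rownames(roc_report) <- NULL

  paths <- c(selection = file.path(config$out_dir,
                                   "selection_report.csv"),
             appearance = file.path(config$out_dir,
                                    "appearance_rates.csv"),
             roc = file.path(config$out_dir, "roc_report.csv"),
             exclusions = file.path(config$out_dir, "exclusions.csv"),
             config = file.path(config$out_dir,
                                "config_snapshot.txt"))
  utils::write.csv(selection_report, paths["selection"],
                   row.names = FALSE)
  utils::write.csv(appearance_report, paths["appearance"],
                   row.names = FALSE)
  utils::write.csv(roc_report, paths["roc"], row.names = FALSE)
  utils::write.csv(exclusions, paths["exclusions"],
                   row.names = FALSE)
  writeLines(.serialize_config(config), paths["config"])

  invisible(structure(list(selection_report = selection_report,
                           appearance_report = appearance_report,
                           roc_report = roc_report,
                           exclusions = exclusions,
                           selections = selections,
                           table = table, sim = sim,
                           forbidden = forb, paths = paths),
                      class = "ddk_pipeline_result"))
}

#' @export
print.ddk_pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<ddk_pipeline_result> %d selection rows (%d significant), %d ROC rows\n",
    nrow(x$selection_report),
    sum(x$selection_report$significant, na.rm = TRUE),
    nrow(x$roc_report)))
  cat("  outputs:", dirname(x$paths[["selection"]]), "\n")
  invisible(x)
}

#' Paired null vs null+features group classification
#'
#' Fits the two logistic models on the shared complete-case set
#' (covariates only vs covariates plus all motor-speech features; the
#' forbidden-pair constraint is deliberately not applied — all
#' features enter, collinear fits accepted) and compares their ROC
#' curves with the paired placement-value test.
#'
#' @param data Analysis frame with `group`, covariates and features.
#' @param null_covariates,features Predictor column names.
#' @return A `ddk_roc_comparison`.
#' @export
compare_group_classifiers <- function(data, null_covariates,
                                      features) {
  keep <- stats::complete.cases(
    data[, c(null_covariates, features), drop = FALSE]) &
    !is.na(data$group)
  d <- data[keep, , drop = FALSE]
  f_null <- fit_logistic(d, null_covariates)
  f_full <- fit_logistic(d, c(null_covariates, features))
  delong_compare(f_null$scores, f_full$scores, f_null$labels)
}

# synthesize + screen + extract features for every non-missing
# (participant, test); seeds derive deterministically from the master
.extract_cohort_audio <- function(sim, config) {
  p <- sim$params[!sim$params$missing, , drop = FALSE]
  excl <- list(); rows <- list()
  for (i in seq_len(nrow(p))) {
    r <- p[i, ]
    spec <- syllable_train_spec(
      sample_rate = config$synth_rate,
      duration = sim$truth$spec$duration,
      n_repetitions = 80,          # truncated by duration
      ioi_mean = r$ioi_mean, ioi_sd = r$ioi_sd,
      ioi_drift = r$ioi_drift,
      syllable_duration = r$syllable_duration,
      vot = r$vot, vowel_f0 = r$vowel_f0, snr_db = r$snr_db,
      seed = (config$seed * 1009L + i * 31L) %% 2147483647L)
    syn <- synthesize_ddk_recording(spec)
    rec <- syn$recording
    rec$test_label <- r$test
    rec$participant_id <- r$participant_id
    scr <- screen_recording(rec, min_duration = config$min_duration,
                            utterance_check = FALSE)
    if (!scr$admitted) {
      excl[[i]] <- data.frame(participant_id = r$participant_id,
                              test = r$test, reason = scr$reason,
                              stringsAsFactors = FALSE)
      next
    }
    fv <- extract_features(rec, denoise_audio = config$denoise_audio)
    rows[[i]] <- cbind(data.frame(participant_id = r$participant_id,
                                  test = r$test,
                                  stringsAsFactors = FALSE),
                       as.data.frame(as.list(fv)))
  }
  list(features = do.call(rbind, rows),
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(participant_id = character(),
                                    test = character(),
                                    reason = character()))
}

.serialize_config <- function(config) {
  flat <- config
  flat$cohort_args <- NULL
  lines <- c(
    vapply(names(flat), function(k)
      sprintf("%s = %s", k, paste(format(flat[[k]]), collapse = ",")),
      character(1)),
    vapply(names(config$cohort_args), function(k)
      sprintf("cohort.%s = %s", k,
              paste(format(config$cohort_args[[k]]), collapse = ",")),
      character(1)))
  lines
}
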