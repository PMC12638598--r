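#' Names of the 19 motor-speech features
#'
#' The full feature panel, grouped by underlying quality: onset
#' (`onset_count`, `onset_rate`), inter-onset interval (`ioi_mean`,
#' `ioi_sd`, `inverse_min_ioi`, `decrement_on_ioi`,
#' `inverse_ioi_mean`, `inverse_ioi_cov`), syllable
#' (`articulation_rate`, `syllable_duration_mean`,
#' `syllable_duration_cov`, `speech_percent`,
#' `speech_to_pause_ratio`), pause (`pause_mean`, `pause_cov`,
#' `pause_percent`), voice onset (`vot_mean`, `vot_cov`) and energy
#' (`onset_strength_cov`).
#'
#' @return Character vector of length 19.
#' @export
ddk_feature_names <- function() {
  c("onset_count", "onset_rate", "ioi_mean", "ioi_sd",
    "inverse_min_ioi", "decrement_on_ioi", "inverse_ioi_mean",
    "inverse_ioi_cov", "articulation_rate", "syllable_duration_mean",
    "syllable_duration_cov", "speech_percent", "speech_to_pause_ratio",
    "pause_mean", "pause_cov", "pause_percent", "vot_mean", "vot_cov",
    "onset_strength_cov")
}

#' Extract the 19-feature motor-speech profile from one recording
#'
#' Runs the full per-recording analysis chain: resample to the
#' internal analysis rate, spectral-gating denoise, peak
#' normalization, onset detection (onset/IOI/energy features), and
#' speech--pause segmentation with voice-onset-time measurement
#' (syllable/pause/VOT features).
#'
#' @param rec A [ddk_recording].
#' @param denoise_audio Apply noise reduction first? (default `TRUE`)
#' @param analysis_rate Internal sample rate, Hz.
#' @param ... Passed on to [detect_onsets()].
#' @return Named numeric vector over [ddk_feature_names()]; entries
#'   whose defining event set is empty are `NA`.
#' @export
extract_features <- function(rec, denoise_audio = TRUE,
                             analysis_rate = 16000, ...) {
  stopifnot(inherits(rec, "ddk_recording"))
  rec <- resample_recording(rec, analysis_rate)
  if (max(abs(rec$samples)) == 0)
    return(stats::setNames(rep(NA_real_, 19), ddk_feature_names()))
  rec <- normalize(rec)
  if (denoise_audio) rec <- normalize(denoise(rec))

  env <- onset_strength_envelope(rec)
  onsets <- detect_onsets(env, refine = rec, ...)
  f_onset <- onset_ioi_features(onsets, duration(rec))

  segments <- segment_speech_pause(rec)
  vots <- measure_vot(rec, segments)
  f_timing <- timing_features(segments, vots)

  out <- c(f_onset, f_timing)[ddk_feature_names()]
  names(out) <- ddk_feature_names()
  out
}

#' Assemble a cohort analysis table
#'
#' Merges per-recording feature vectors with participant covariates
#' and outcomes into one analysis container.  Participants with no
#' usable recording for a test carry `NA` features for that test;
#' analyses of the other tests are unaffected.
#'
#' @param features A data frame with columns `participant_id`, `test`
#'   (one of `"pa"`, `"ta"`, `"ka"`) and the 19 feature columns; at
#'   most one row per participant and test.
#' @param cohort A data frame with one row per participant:
#'   `participant_id`, `group` (`"HC"`/`"SCI"`), covariates `age`,
#'   `sex`, `education`, `psychiatric`, `hads_anxiety`,
#'   `hads_depression`, and count outcomes `episodic_memory`,
#'   `executive_strategy`, `working_memory`.
#' @return An object of class `ddk_cohort` with elements `cohort` and
#'   `features`.
#' @export
build_feature_table <- function(features, cohort) {
  need <- c("participant_id", "group", "age", "sex", "education",
            "psychiatric", "hads_anxiety", "hads_depression",
            "episodic_memory", "executive_strategy", "working_memory")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$participant_id))
    stop("duplicated participant ids in cohort: ",
         paste(unique(cohort$participant_id[
           duplicated(cohort$participant_id)]), collapse = ", "))
  if (nrow(features)) {
    unknown <- setdiff(features$participant_id, cohort$participant_id)
    if (length(unknown))
      stop("feature rows reference unknown participants: ",
           paste(unique(unknown), collapse = ", "))
    key <- paste(features$participant_id, features$test)
    if (anyDuplicated(key))
      stop("duplicated (participant, test) feature rows: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  structure(list(cohort = cohort, features = features),
            class = "ddk_cohort")
}

#' @export
print.ddk_cohort <- function(x, ...) {
  cat(sprintf("<ddk_cohort> %d participants (%s)",
              nrow(x$cohort),
              paste(sprintf("%s: %d", names(table(x$cohort$group)),
                            table(x$cohort$group)), collapse = ", ")))
  cat(sprintf("; %d feature rows across tests %s\n", nrow(x$features),
              paste(sort(unique(x$features$test)), collapse = "/")))
  invisible(x)
}

# analysis frame for one (test, group): covariates + outcomes + features
.analysis_frame <- function(table, test_label, group = NULL) {
  stopifnot(inherits(table, "ddk_cohort"))
  f <- table$features[table$features$test == test_label, , drop = FALSE]
  d <- merge(table$cohort, f[, c("participant_id", ddk_feature_names())],
             by = "participant_id", all.x = FALSE)
  if (!is.null(group)) d <- d[d$group %in% group, , drop = FALSE]
  d
}

#' Pairwise Pearson correlation matrix of features (and outcomes)
#'
#' Computes Pearson correlations on pairwise-complete observations
#' over the 19 features, optionally including the three cognitive
#' outcomes, within one test and analysis group.  Constant columns
#' get `NA` correlations.
#'
#' @param table A `ddk_cohort` from [build_feature_table()].
#' @param test_label `"pa"`, `"ta"` or `"ka"`.
#' @param group `"HC"`, `"SCI"`, or `NULL` for pooled.
#' @param include_outcomes Append the outcome columns?
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, test_label, group = NULL,
                               include_outcomes = FALSE) {
  d <- .analysis_frame(table, test_label, group)
  cols <- ddk_feature_names()
  if (include_outcomes)
    cols <- c(cols, "episodic_memory", "executive_strategy",
              "working_memory")
  m <- as.matrix(d[, cols, drop = FALSE])
  if (sum(stats::complete.cases(m)) < 3)
    stop("fewer than 3 complete cases for ", test_label)
  suppressWarnings(
    r <- stats::cor(m, use = "pairwise.complete.obs",
                    method = "pearson"))
  diag(r) <- 1
  r
}

#' Feature pairs barred from joint inclusion in one model
#'
#' Implements the collinearity exclusion rule: an unordered feature
#' pair is forbidden from appearing together in any single model if
#' its absolute pairwise correlation exceeds `threshold` in *all
#' three* DDK tests.  (Strict inequality; absolute correlation,
#' since collinearity is sign-agnostic.)  A pair with an undefined
#' correlation in any test is treated as not exceeding the threshold
#' (kept selectable).
#'
#' @param cor_pa,cor_ta,cor_ka Correlation matrices over identical
#'   feature names, e.g. from [correlation_matrix()].
#' @param threshold Exclusion threshold (default 0.6).
#' @return An object of class `ddk_forbidden_pairs`: a two-column
#'   character matrix of feature-name pairs (lexicographically
#'   ordered within and across rows).
#' @export
forbidden_pairs <- function(cor_pa, cor_ta, cor_ka, threshold = 0.6) {
  feats <- intersect(ddk_feature_names(), rownames(cor_pa))
  stopifnot(all(feats %in% rownames(cor_ta)),
            all(feats %in% rownames(cor_ka)))
  pairs <- utils::combn(sort(feats), 2)
  bad <- apply(pairs, 2, function(p) {
    rs <- c(cor_pa[p[1], p[2]], cor_ta[p[1], p[2]], cor_ka[p[1], p[2]])
    if (anyNA(rs)) return(FALSE)
    all(abs(rs) > threshold)
  })
  structure(t(pairs[, bad, drop = FALSE]),
            class = "ddk_forbidden_pairs")
}

#' @export
print.ddk_forbidden_pairs <- function(x, ...) {
  cat(sprintf("<ddk_forbidden_pairs> %d excluded pairs\n", nrow(x)))
  if (nrow(x))
    cat(paste0("  ", x[, 1], " -- ", x[, 2], collapse = "\n"), "\n")
  invisible(x)
}

#' Write / read the per-recording feature table as CSV
#'
#' Missing values are encoded as empty fields.
#'
#' @param features Feature data frame (see [build_feature_table()]).
#' @param path Output path.
#' @return `path` invisibly; `read_feature_csv` returns a data frame.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
}
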