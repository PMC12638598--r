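make_feature_rows <- function(ids, tests, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(participant_id = ids, test = tests,
                      stringsAsFactors = FALSE)
  feats <- matrix(stats::rnorm(nrow(grid) * 19), nrow(grid), 19,
                  dimnames = list(NULL, ddk_feature_names()))
  cbind(grid, as.data.frame(feats))
}

make_cohort_rows <- function(ids, seed = 2) {
  set.seed(seed)
  n <- length(ids)
  data.frame(participant_id = ids,
             group = rep(c("HC", "SCI"), length.out = n),
             age = round(stats::rnorm(n, 67, 7)),
             sex = sample(c("F", "M"), n, TRUE),
             education = sample(1:5, n, TRUE),
             psychiatric = stats::rbinom(n, 1, 0.2),
             hads_anxiety = stats::rpois(n, 5),
             hads_depression = stats::rpois(n, 2),
             episodic_memory = stats::rpois(n, 4),
             executive_strategy = stats::rpois(n, 8),
             working_memory = stats::rpois(n, 3),
             stringsAsFactors = FALSE)
}

test_that("feature tables assemble one row per participant and test", {
  ids <- c("a", "b", "c")
  tab <- build_feature_table(make_feature_rows(ids, c("pa", "ta", "ka")),
                             make_cohort_rows(ids))
  expect_s3_class(tab, "ddk_cohort")
  expect_equal(nrow(tab$features), 9)

  # a missing "ta" recording leaves other tests unaffected
  f <- make_feature_rows(ids, c("pa", "ta", "ka"))
  f <- f[!(f$participant_id == "b" & f$test == "ta"), ]
  tab2 <- build_feature_table(f, make_cohort_rows(ids))
  d_ta <- ddktools:::.analysis_frame(tab2, "ta")
  d_pa <- ddktools:::.analysis_frame(tab2, "pa")
  expect_equal(nrow(d_ta), 2)
  expect_equal(nrow(d_pa), 3)
})

test_that("assembly enforces identifier integrity", {
  ids <- c("a", "b", "c")
  cohort <- make_cohort_rows(ids)
  feats <- make_feature_rows(c(ids, "ghost"), "pa")
  expect_error(build_feature_table(feats, cohort), "ghost")

  dup_cohort <- rbind(cohort, cohort[1, ])
  expect_error(build_feature_table(make_feature_rows(ids, "pa"),
                                   dup_cohort), "duplicated")

  dup_feats <- rbind(make_feature_rows(ids, "pa"),
                     make_feature_rows("a", "pa"))
  expect_error(build_feature_table(dup_feats, cohort), "duplicated")
})

test_that("correlation matrices behave like Pearson correlation", {
  ids <- sprintf("p%03d", 1:60)
  f <- make_feature_rows(ids, c("pa", "ta", "ka"), seed = 3)
  # plant an exact duplicate and an exact negation
  f$ioi_sd <- f$ioi_mean
  f$pause_mean <- -f$ioi_mean
  tab <- build_feature_table(f, make_cohort_rows(ids))
  r <- correlation_matrix(tab, "pa")
  expect_equal(unname(r["ioi_mean", "ioi_sd"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["ioi_mean", "pause_mean"]), -1,
               tolerance = 1e-12)
  expect_true(isSymmetric(unname(r)))
  expect_true(all(diag(r) == 1))

  # constant column: correlations undefined, not an error
  f2 <- make_feature_rows(ids, "pa", seed = 4)
  f2$vot_cov <- 1
  tab2 <- build_feature_table(f2, make_cohort_rows(ids))
  r2 <- correlation_matrix(tab2, "pa")
  expect_true(all(is.na(r2["vot_cov", setdiff(colnames(r2),
                                              "vot_cov")])))
})

test_that("independent features stay uncorrelated at large n", {
  ids <- sprintf("p%04d", 1:5000)
  tab <- build_feature_table(make_feature_rows(ids, "pa", seed = 5),
                             make_cohort_rows(ids))
  r <- correlation_matrix(tab, "pa")
  off <- abs(r[upper.tri(r)])
  expect_lt(max(off), 0.07)
})

test_that("the forbidden-pair rule requires exceedance in all three tests", {
  base <- diag(19)
  dimnames(base) <- list(ddk_feature_names(), ddk_feature_names())
  with_r <- function(r) {
    m <- base
    m["ioi_mean", "ioi_sd"] <- m["ioi_sd", "ioi_mean"] <- r
    m
  }
  # high in all three: forbidden
  fp <- forbidden_pairs(with_r(0.9), with_r(-0.9), with_r(0.9))
  expect_equal(nrow(fp), 1)
  expect_setequal(as.character(fp[1, ]), c("ioi_mean", "ioi_sd"))
  # high in only two: allowed
  fp2 <- forbidden_pairs(with_r(0.9), with_r(0.9), with_r(0.3))
  expect_equal(nrow(fp2), 0)
  # strict inequality at the boundary
  expect_equal(nrow(forbidden_pairs(with_r(0.61), with_r(0.61),
                                    with_r(0.61))), 1)
  expect_equal(nrow(forbidden_pairs(with_r(0.60), with_r(0.60),
                                    with_r(0.60))), 0)
  # undefined correlation in one test: conservatively selectable
  m_na <- with_r(NA_real_)
  expect_equal(nrow(forbidden_pairs(with_r(0.9), m_na, with_r(0.9))),
               0)
})

test_that("forbidden pairs are invariant to row order of the table", {
  ids <- sprintf("p%03d", 1:80)
  f <- make_feature_rows(ids, c("pa", "ta", "ka"), seed = 6)
  f$onset_rate <- f$onset_count * 0.1 +
    stats::rnorm(nrow(f), 0, 0.01)
  cohort <- make_cohort_rows(ids)
  tab <- build_feature_table(f, cohort)
  fp1 <- forbidden_pairs(correlation_matrix(tab, "pa"),
                         correlation_matrix(tab, "ta"),
                         correlation_matrix(tab, "ka"))
  shuffle <- sample(nrow(f))
  tab2 <- build_feature_table(f[shuffle, ], cohort)
  fp2 <- forbidden_pairs(correlation_matrix(tab2, "pa"),
                         correlation_matrix(tab2, "ta"),
                         correlation_matrix(tab2, "ka"))
  expect_equal(unclass(fp1), unclass(fp2))
  expect_gte(nrow(fp1), 1)
})

test_that("feature CSV round-trips preserve missing values", {
  ids <- c("a", "b")
  f <- make_feature_rows(ids, "pa")
  f$vot_mean[1] <- NA
  path <- tempfile(fileext = ".csv")
  write_feature_csv(f, path)
  f2 <- read_feature_csv(path)
  expect_true(is.na(f2$vot_mean[1]))
  expect_equal(f2$ioi_mean, f$ioi_mean, tolerance = 1e-12)
})
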