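# Exclusion rules, Little's MCAR test, imputation, and the paired
# stopping-rule comparison.

make_exclusion_fixture <- function() {
  # 100 lesions: 8 duration violations, 6 ILD violations, 1 overlapping
  # (row 8 violates both), so 13 rows fall and 87 survive
  set.seed(19)
  tab <- data.frame(lesion_id = sprintf("L%03d", 1:100),
                    duration_li_s = stats::runif(100, 5, 25),
                    ild_mm = stats::runif(100, 1, 5.5))
  tab$duration_li_s[1:8] <- stats::runif(8, 30.5, 40)
  tab$ild_mm[8:13] <- stats::runif(6, 6.5, 9)
  tab
}

test_that("exclusion rules are strict-over and boundary-retaining", {
  cfg <- exclusion_config()
  ok <- data.frame(duration_li_s = rep(29, 5), ild_mm = rep(5, 5))
  expect_identical(nrow(apply_exclusions(ok, cfg)), 5L)
  boundary <- data.frame(duration_li_s = c(30, 30.0001),
                         ild_mm = c(6, 5))
  kept <- apply_exclusions(boundary, cfg)
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$duration_li_s, 30)
})

test_that("a constructed fixture loses exactly its known violations", {
  tab <- make_exclusion_fixture()
  kept <- apply_exclusions(tab)
  log <- attr(kept, "exclusion_log")
  expect_identical(nrow(kept), 87L)
  expect_identical(log$n_over_duration, 8L)
  expect_identical(log$n_over_ild, 6L)
  expect_identical(log$n_overlap, 1L)
  expect_identical(log$n_excluded, 13L)
  expect_equal(log$excluded_fraction, 0.13)
})

test_that("exclusion is idempotent and NA ILDs are retained", {
  tab <- make_exclusion_fixture()
  tab$ild_mm[20] <- NA
  once <- apply_exclusions(tab)
  twice <- apply_exclusions(once)
  expect_equal(as.data.frame(once), as.data.frame(twice), ignore_attr = TRUE)
  expect_true("L020" %in% once$lesion_id)
})

test_that("Little's test is undefined for a single missingness pattern", {
  X <- matrix(stats::rnorm(200), 50, 4)
  out <- little_mcar_test(X)
  expect_identical(out$n_patterns, 1L)
  expect_true(is.na(out$chi2))
})

test_that("Little's test is calibrated under MCAR and powered under MAR", {
  # null calibration in the asymptotic regime
  set.seed(20)
  rej_null <- mean(replicate(200, {
    X <- matrix(stats::rnorm(4000), 1000, 4)
    X[, 1] <- X[, 1] + 0.5 * X[, 2]
    X[stats::runif(1000) < 0.2, 1] <- NA
    little_mcar_test(X)$p_value < 0.05
  }))
  expect_gte(rej_null, 0.03)
  expect_lte(rej_null, 0.08)

  # strong MAR: missingness driven by an observed covariate
  set.seed(21)
  rej_mar <- mean(replicate(50, {
    X <- matrix(stats::rnorm(2000), 500, 4)
    X[, 1] <- X[, 1] + 0.5 * X[, 2]
    X[stats::runif(500) < stats::plogis(-2 + 2 * X[, 2]), 1] <- NA
    little_mcar_test(X)$p_value < 0.05
  }))
  expect_gt(rej_mar, 0.8)
})

test_that("imputation is the identity with nothing missing and never
           alters observed cells", {
  tab <- make_mar_fixture(31, n = 150, rate = 0)
  out <- impute_durations(tab, "mice", seed = 1)
  expect_equal(out$completed$duration_lsi_s, tab$duration_lsi_s)

  tab2 <- make_mar_fixture(32)
  for (mth in c("mice", "mean", "median", "knn")) {
    res <- impute_durations(tab2, mth, seed = 2)
    obs <- !res$missing
    expect_equal(res$completed$duration_lsi_s[obs],
                 tab2$duration_lsi_s[obs])
    expect_false(anyNA(res$completed$duration_lsi_s))
  }
})

test_that("chained-equations imputation tracks the truth better than the mean", {
  tab <- make_mar_fixture(33)
  mask <- attr(tab, "mask")
  truth <- mask$truth[mask$missing]
  mi <- impute_durations(tab, "mice", seed = 3)
  mn <- impute_durations(tab, "mean", seed = 3)
  r_mice <- stats::cor(mi$imputed_values, truth)
  r_mean_resid <- stats::cor(mn$imputed_values + stats::rnorm(length(truth), 0, 1e-9),
                             truth)
  expect_gt(r_mice, 0.5)
  expect_gt(r_mice, abs(r_mean_resid))
  expect_lt(mean(abs(mi$imputed_values - truth)),
            mean(abs(mn$imputed_values - truth)))
})

test_that("iteration count barely moves the pooled medians", {
  tab <- make_mar_fixture(34)
  meds <- vapply(c(5L, 10L, 15L), function(it)
    stats::median(impute_durations(tab, "mice", iterations = it,
                                   seed = 4)$completed$duration_lsi_s),
    numeric(1))
  expect_lt((max(meds) - min(meds)) / min(meds), 0.05)
})

test_that("the sensitivity report covers all methods and runs Little's test", {
  tab <- make_mar_fixture(35, n = 200)
  rep <- imputation_sensitivity(tab, seed = 5)
  expect_named(rep$completions, c("mice", "mean", "median", "knn"))
  expect_identical(nrow(rep$agreement), 3L)
  expect_true(all(is.finite(rep$agreement$mae)))
  expect_true(is.finite(rep$mcar$chi2))
  expect_identical(rep$mcar$n_patterns, 2L)
})

test_that("identical duration columns give a null Friedman result", {
  d <- stats::runif(20, 5, 25)
  tab <- data.frame(duration_li_s = d, duration_ai_s = d, duration_lsi_s = d)
  cmp <- suppressWarnings(compare_durations(tab))
  expect_equal(cmp$friedman_chi2, 0)
  expect_equal(cmp$friedman_p, 1)
  expect_true(all(cmp$pairwise$effect_size_r == 0))
})

test_that("small-table statistics match exhaustive enumeration oracles", {
  set.seed(22)
  for (rep_i in 1:5) {
    M <- matrix(stats::rnorm(24, 10, 3), 8, 3)
    colnames(M) <- c("duration_li_s", "duration_ai_s", "duration_lsi_s")
    cmp <- compare_durations(as.data.frame(M))
    expect_equal(cmp$friedman_chi2, friedman_bruteforce(M), tolerance = 1e-9)
    for (k in 1:3) {
      pr <- strsplit(cmp$pairwise$pair[k], " vs ")[[1]]
      d <- M[, pr[1]] - M[, pr[2]]
      expect_equal(cmp$pairwise$p_raw[k], signed_rank_exact_p(d),
                   tolerance = 1e-9)
      r <- rank(abs(d))
      expect_equal(cmp$pairwise$W[k], sum(r[d > 0]))
    }
  }
})

test_that("the comparison stage holds its type-I error on exchangeable nulls", {
  set.seed(23)
  rej <- mean(replicate(500, {
    M <- matrix(stats::rnorm(90, 12, 3), 30, 3)
    colnames(M) <- c("duration_li_s", "duration_ai_s", "duration_lsi_s")
    suppressWarnings(compare_durations(as.data.frame(M)))$friedman_p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("effect sizes are bounded, signed by the median difference,
           and Bonferroni factors capped", {
  set.seed(24)
  M <- data.frame(duration_li_s = stats::rnorm(40, 12, 1),
                  duration_ai_s = stats::rnorm(40, 7, 1),
                  duration_lsi_s = stats::rnorm(40, 20, 1))
  cmp <- compare_durations(M)
  expect_true(all(abs(cmp$pairwise$effect_size_r) <= 1))
  # LI - AI positive, LI - LSI negative, AI - LSI negative
  expect_gt(cmp$pairwise$effect_size_r[1], 0)
  expect_lt(cmp$pairwise$effect_size_r[2], 0)
  expect_lt(cmp$pairwise$effect_size_r[3], 0)
  expect_true(all(cmp$pairwise$p_bonferroni <= 1))
  expect_true(all(cmp$pairwise$p_bonferroni >= cmp$pairwise$p_raw))
})

test_that("cohort summaries use linear-interpolation quantiles", {
  tab <- data.frame(duration_li_s = c(1, 2, 3, 4, 5))
  s <- summarize_cohort(tab, "duration_li_s")
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  s2 <- summarize_cohort(data.frame(x = rep(7, 10)), "x")
  expect_equal(s2$median, 7)
  expect_equal(s2$q3 - s2$q1, 0)
})
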