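# Cohort-level analysis: exclusion rules, Little's MCAR test,
# chained-equations imputation of missing LSI durations with mean/median/kNN
# comparators, and the paired Friedman + post-hoc Wilcoxon comparison of RF
# application durations across the three stopping rules.

#' Exclusion configuration
#'
#' @param max_duration_s lesions whose delivered (LI-guided) RF duration
#'   exceeds this are excluded (default 30 s; boundary retained).
#' @param max_ild_mm lesions whose interlesion distance exceeds this are
#'   excluded (default 6 mm; boundary retained).
#' @return An object of class `exclusion_config`.
#' @export
exclusion_config <- function(max_duration_s = 30, max_ild_mm = 6) {
  if (max_duration_s <= 0 || max_ild_mm <= 0)
    stop("exclusion_config: thresholds must be positive", call. = FALSE)
  structure(list(max_duration_s = max_duration_s, max_ild_mm = max_ild_mm),
            class = "exclusion_config")
}

#' Apply the cohort exclusion rules
#'
#' Retains lesions with delivered RF duration `<= max_duration_s` AND
#' interlesion distance `<= max_ild_mm` ("over" is strict, so boundary
#' values stay). Lesions with undefined ILD (singleton procedures) are not
#' excluded by the distance rule. Filters commute and the operation is
#' idempotent.
#'
#' @param lesions lesion-summary data frame (needs `duration_li_s`,
#'   `ild_mm`).
#' @param cfg an [exclusion_config()].
#' @return The retained table, with attribute `exclusion_log`: per-rule
#'   counts, overlap, and the combined excluded fraction.
#' @export
apply_exclusions <- function(lesions, cfg = exclusion_config()) {
  stopifnot(inherits(cfg, "exclusion_config"))
  if (!all(c("duration_li_s", "ild_mm") %in% names(lesions)))
    stop("apply_exclusions: duration_li_s and ild_mm columns required",
         call. = FALSE)
  over_dur <- !is.na(lesions$duration_li_s) &
    lesions$duration_li_s > cfg$max_duration_s
  over_ild <- !is.na(lesions$ild_mm) & lesions$ild_mm > cfg$max_ild_mm
  drop <- over_dur | over_ild
  out <- lesions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- list(
    n_input = nrow(lesions),
    n_over_duration = sum(over_dur),
    n_over_ild = sum(over_ild),
    n_overlap = sum(over_dur & over_ild),
    n_excluded = sum(drop),
    n_retained = nrow(out),
    excluded_fraction = if (nrow(lesions)) sum(drop) / nrow(lesions) else 0
  )
  out
}

# ---- Little's MCAR test -------------------------------------------------

# EM for multivariate-normal mean/covariance with missing entries
em_norm <- function(X, max_iter = 100L, tol = 1e-7) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X, na.rm = TRUE)
  S <- stats::cov(X, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  diag(S)[diag(S) <= 0] <- 1
  # make sure S is positive definite to start
  S <- S + diag(1e-6 * mean(diag(S)), p)
  obs_mask <- !is.na(X)
  pattern <- apply(obs_mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  pat_rows <- split(seq_len(n), pattern)
  for (it in seq_len(max_iter)) {
    sum_x <- matrix(0, n, p)
    sum_cc <- matrix(0, p, p)   # accumulated conditional covariances
    for (rows in pat_rows) {
      o <- obs_mask[rows[1L], ]
      m <- !o
      Xo <- X[rows, o, drop = FALSE]
      if (!any(m)) { sum_x[rows, ] <- as.matrix(X[rows, , drop = FALSE]); next }
      if (!any(o)) {
        sum_x[rows, ] <- matrix(mu, length(rows), p, byrow = TRUE)
        sum_cc[m, m] <- sum_cc[m, m] + length(rows) * S[m, m]
        next
      }
      Soo_inv <- solve(S[o, o, drop = FALSE])
      B <- S[m, o, drop = FALSE] %*% Soo_inv
      cond_mean <- matrix(mu[m], length(rows), sum(m), byrow = TRUE) +
        sweep(Xo, 2L, mu[o]) %*% t(B)
      filled <- matrix(NA_real_, length(rows), p)
      filled[, o] <- Xo
      filled[, m] <- cond_mean
      sum_x[rows, ] <- filled
      cond_cov <- S[m, m, drop = FALSE] - B %*% S[o, m, drop = FALSE]
      idx <- which(m)
      sum_cc[idx, idx] <- sum_cc[idx, idx] + length(rows) * cond_cov
    }
    mu_new <- colMeans(sum_x)
    centred <- sweep(sum_x, 2L, mu_new)
    S_new <- (crossprod(centred) + sum_cc) / n
    delta <- max(abs(mu_new - mu), abs(S_new - S))
    mu <- mu_new; S <- S_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = S, patterns = pat_rows, obs_mask = obs_mask)
}

#' Little's MCAR test
#'
#' Tests whether the data are Missing Completely At Random: ML estimates of
#' the mean and covariance are obtained by EM, then each missingness
#' pattern's observed-variable mean is compared to the grand mean by a
#' Mahalanobis distance; the summed statistic is chi-square with
#' \eqn{\sum_j p_j - p} degrees of freedom under MCAR.
#'
#' @param data data frame or matrix of numeric variables with missing
#'   entries.
#' @return A list: `chi2`, `df`, `p_value`, `n_patterns`. With a single
#'   missingness pattern the test is undefined and all values are `NA`
#'   (with `n_patterns = 1`).
#' @export
little_mcar_test <- function(data) {
  X <- as.matrix(as.data.frame(data))
  storage.mode(X) <- "double"
  keep <- apply(X, 1L, function(r) any(is.finite(r)))
  X <- X[keep, , drop = FALSE]
  p <- ncol(X)
  em <- em_norm(X)
  pats <- em$patterns
  if (length(pats) < 2L)
    return(list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                n_patterns = length(pats)))
  chi2 <- 0
  df <- 0L
  for (rows in pats) {
    o <- em$obs_mask[rows[1L], ]
    if (!any(o)) next
    nj <- length(rows)
    xbar <- colMeans(X[rows, o, drop = FALSE])
    d <- xbar - em$mu[o]
    chi2 <- chi2 + nj * drop(t(d) %*% solve(em$sigma[o, o, drop = FALSE], d))
    df <- df + sum(o)
  }
  df <- df - p
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       n_patterns = length(pats))
}

# ---- imputation ---------------------------------------------------------

# one predictive-mean-matching draw for a single target column
pmm_impute_once <- function(y, X, donors = 5L) {
  obs <- !is.na(y)
  Xo <- cbind(1, X[obs, , drop = FALSE])
  Xm <- cbind(1, X[!obs, , drop = FALSE])
  yo <- y[obs]
  fit <- stats::lm.fit(Xo, yo)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  resid <- fit$residuals
  dfres <- max(1L, length(yo) - sum(!is.na(fit$coefficients)))
  sigma2 <- sum(resid^2) / dfres
  # approximate Bayesian draw of the coefficients
  XtX <- crossprod(Xo)
  XtX_inv <- tryCatch(solve(XtX + diag(1e-8, ncol(Xo))),
                      error = function(e) diag(1e6, ncol(Xo)))
  sigma2_star <- sigma2 * dfres / stats::rchisq(1, dfres)
  beta_star <- beta + drop(chol(sigma2_star * XtX_inv +
                                diag(1e-12, ncol(Xo))) %*%
                           stats::rnorm(ncol(Xo)))
  pred_obs <- drop(Xo %*% beta)
  pred_mis <- drop(Xm %*% beta_star)
  out <- y
  k <- min(donors, length(yo))
  for (i in seq_along(pred_mis)) {
    nn <- order(abs(pred_obs - pred_mis[i]))[seq_len(k)]
    out[which(!obs)[i]] <- yo[sample(nn, 1L)]
  }
  out
}

knn_impute_column <- function(y, X, k = 5L) {
  obs <- !is.na(y)
  Xs <- scale(X)
  Xs[!is.finite(Xs)] <- 0
  out <- y
  mis_idx <- which(!obs)
  obs_idx <- which(obs)
  for (i in mis_idx) {
    d <- sqrt(rowSums((Xs[obs_idx, , drop = FALSE] -
                         matrix(Xs[i, ], length(obs_idx), ncol(Xs),
                                byrow = TRUE))^2))
    nn <- obs_idx[order(d)[seq_len(min(k, length(obs_idx)))]]
    out[i] <- mean(y[nn])
  }
  out
}

#' Impute missing LSI durations
#'
#' Fills the missing entries of `target_column` by chained-equations
#' imputation (`"mice"`: iterated predictive-mean-matching regression on
#' the other lesion covariates, `iterations` sweeps, `m` completed copies
#' pooled by their cell-wise mean) or by the `"mean"`, `"median"`, or
#' `"knn"` comparators used in the sensitivity analysis. Observed cells are
#' never altered.
#'
#' @param table lesion-summary data frame.
#' @param method `"mice"`, `"mean"`, `"median"`, or `"knn"`.
#' @param target_column column with missing entries
#'   (default `duration_lsi_s`).
#' @param predictors covariate columns used by `"mice"`/`"knn"`; defaults
#'   to the observed lesion covariates.
#' @param iterations chained-equation sweeps (default 5).
#' @param m number of imputation chains pooled (default 5).
#' @param seed integer seed.
#' @param knn_k neighbours for `"knn"` (default 5).
#' @return A list of class `imputation_result`: `completed` (the table with
#'   the target filled), `imputed_values`, `missing` (logical index),
#'   `method`, `iterations`.
#' @export
impute_durations <- function(table, method = c("mice", "mean", "median", "knn"),
                             target_column = "duration_lsi_s",
                             predictors = c("duration_li_s", "duration_ai_s",
                                            "cf_mean_g", "li_drop_ohm",
                                            "li_start_ohm"),
                             iterations = 5L, m = 5L, seed = 1L, knn_k = 5L) {
  method <- match.arg(method)
  y <- table[[target_column]]
  if (is.null(y)) stop("impute_durations: target column not found", call. = FALSE)
  miss <- is.na(y)
  if (all(miss)) stop("impute_durations: target column entirely missing",
                      call. = FALSE)
  if (!any(miss)) {
    return(structure(list(completed = table, imputed_values = numeric(0),
                          missing = miss, method = method,
                          iterations = iterations),
                     class = "imputation_result"))
  }
  predictors <- intersect(predictors, names(table))
  X <- as.matrix(table[, predictors, drop = FALSE])
  complete_pred <- apply(X, 2L, function(col) all(is.finite(col)))
  X <- X[, complete_pred, drop = FALSE]
  if (method %in% c("mice", "knn") && ncol(X) == 0L)
    stop("impute_durations: no fully observed predictor columns", call. = FALSE)

  old <- get_global_rng_state()
  set.seed(seed)
  on.exit(restore_rng_state(old), add = TRUE)
  filled <- switch(method,
    mean = { z <- y; z[miss] <- mean(y[!miss]); z },
    median = { z <- y; z[miss] <- stats::median(y[!miss]); z },
    knn = knn_impute_column(y, X, k = knn_k),
    mice = {
      chains <- matrix(NA_real_, sum(miss), m)
      for (chain in seq_len(m)) {
        z <- y
        z[miss] <- sample(y[!miss], sum(miss), replace = TRUE)  # random start
        for (it in seq_len(iterations)) {
          z <- ifelse(miss, pmm_impute_once(y, X), z)
        }
        chains[, chain] <- z[miss]
      }
      z <- y
      z[miss] <- rowMeans(chains)
      z
    })
  completed <- table
  completed[[target_column]] <- filled
  structure(list(completed = completed, imputed_values = filled[miss],
                 missing = miss, method = method, iterations = iterations),
            class = "imputation_result")
}

#' Sensitivity analysis across imputation methods
#'
#' Runs chained-equations imputation alongside the mean, median, and kNN
#' comparators and reports cross-method agreement on the imputed cells only:
#' an R2-style concordance (squared correlation with the chained-equations
#' completion) and an MAE-style discrepancy.
#'
#' @param table lesion-summary data frame with missing target entries.
#' @param target_column,predictors,iterations,seed passed to
#'   [impute_durations()].
#' @return A list of class `imputation_report`: `mcar` (Little's test on
#'   target + predictors), per-method `completions`, and an `agreement`
#'   data frame.
#' @export
imputation_sensitivity <- function(table, target_column = "duration_lsi_s",
                                   predictors = c("duration_li_s",
                                                  "duration_ai_s", "cf_mean_g",
                                                  "li_drop_ohm", "li_start_ohm"),
                                   iterations = 5L, seed = 1L) {
  methods <- c("mice", "mean", "median", "knn")
  fits <- lapply(methods, function(mth)
    impute_durations(table, mth, target_column, predictors,
                     iterations = iterations, seed = seed))
  names(fits) <- methods
  ref <- fits$mice$imputed_values
  agreement <- do.call(rbind, lapply(methods[-1L], function(mth) {
    v <- fits[[mth]]$imputed_values
    data.frame(method = mth,
               concordance_r2 = if (stats::sd(v) > 0 && stats::sd(ref) > 0)
                 stats::cor(ref, v)^2 else NA_real_,
               mae = mean(abs(ref - v)),
               stringsAsFactors = FALSE)
  }))
  pred_cols <- intersect(predictors, names(table))
  mcar <- little_mcar_test(table[, c(target_column, pred_cols), drop = FALSE])
  structure(list(mcar = mcar,
                 completions = lapply(fits, `[[`, "completed"),
                 imputed = lapply(fits, `[[`, "imputed_values"),
                 agreement = agreement),
            class = "imputation_report")
}

# ---- paired comparison --------------------------------------------------

# signed-rank Z with tie correction and continuity correction; zeros dropped
signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(z = 0, W = 0, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(W - mu) * 0.5
  z <- if (sigma2 > 0) (W - mu - cc) / sqrt(sigma2) else 0
  list(z = z, W = W, n = n)
}

#' Compare RF application durations across stopping rules
#'
#' The paired comparison of the three per-lesion durations (LI plateau,
#' AI target, LSI target): a Friedman test on the within-lesion ranks,
#' then the three post-hoc pairwise Wilcoxon signed-rank tests with
#' Bonferroni-multiplied p-values (factor 3, capped at 1) and effect sizes
#' \eqn{r = Z/\sqrt{n}} signed by the median paired difference (first-listed
#' minus second-listed column). Wilcoxon p-values use exact enumeration for
#' 25 or fewer non-zero differences (when untied) and the
#' continuity-corrected normal approximation otherwise; zero differences
#' are dropped.
#'
#' @param durations data frame/matrix with columns `duration_li_s`,
#'   `duration_ai_s`, `duration_lsi_s` (complete cases required; impute
#'   first).
#' @return A list of class `cohort_comparison`: `friedman_chi2`,
#'   `friedman_df`, `friedman_p`, `n_lesions`, `pairwise` (data frame with
#'   `pair`, `W`, `p_raw`, `p_bonferroni`, `effect_size_r`), and `medians`.
#' @export
compare_durations <- function(durations) {
  cols <- c("duration_li_s", "duration_ai_s", "duration_lsi_s")
  if (!all(cols %in% colnames(durations)))
    stop("compare_durations: need columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  M <- as.matrix(as.data.frame(durations)[, cols])
  M <- M[stats::complete.cases(M), , drop = FALSE]
  n <- nrow(M)
  if (n < 5L) stop("compare_durations: need at least 5 complete lesions",
                   call. = FALSE)
  if (all(apply(M, 1L, function(r) length(unique(r)) == 1L)))
    warning("compare_durations: all rows tied; zero-variance comparison")
  fr <- stats::friedman.test(M)
  # with every row fully tied the rank variance is zero: a null result
  if (!is.finite(fr$statistic)) {
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  pairs <- utils::combn(cols, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    d <- M[, pr[1L]] - M[, pr[2L]]
    sr <- signed_rank_z(d)
    nz <- d[d != 0]
    exact_ok <- sr$n > 0 && sr$n <= 25L && !any(duplicated(abs(nz)))
    p_raw <- if (sr$n == 0L) 1 else suppressWarnings(
      stats::wilcox.test(nz, exact = exact_ok, correct = TRUE)$p.value)
    r_eff <- if (n > 0) abs(sr$z) / sqrt(n) else 0
    med_diff <- stats::median(d)
    r_eff <- r_eff * ifelse(med_diff < 0, -1, ifelse(med_diff > 0, 1, 0))
    data.frame(pair = paste(pr, collapse = " vs "),
               W = sr$W, n_nonzero = sr$n, p_raw = p_raw,
               p_bonferroni = min(1, p_raw * length(pairs)),
               effect_size_r = r_eff, stringsAsFactors = FALSE)
  }))
  meds <- do.call(rbind, lapply(cols, function(cn) {
    q <- stats::quantile(M[, cn], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(metric = cn, median = q[2L], q1 = q[1L], q3 = q[3L],
               stringsAsFactors = FALSE)
  }))
  structure(list(
    friedman_chi2 = unname(fr$statistic), friedman_df = unname(fr$parameter),
    friedman_p = fr$p.value, n_lesions = n, pairwise = pw, medians = meds
  ), class = "cohort_comparison")
}

#' Median/IQR summary of a lesion table
#'
#' Per-column median and interquartile range (linear-interpolation
#' quantiles, type 7) for the numeric lesion metrics.
#'
#' @param lesions lesion-summary data frame.
#' @param columns columns to summarise; defaults to the numeric ones.
#' @return Data frame with `metric`, `n`, `median`, `q1`, `q3`.
#' @export
summarize_cohort <- function(lesions, columns = NULL) {
  if (nrow(lesions) == 0L) stop("summarize_cohort: empty table", call. = FALSE)
  if (is.null(columns))
    columns <- names(lesions)[vapply(lesions, is.numeric, TRUE)]
  do.call(rbind, lapply(columns, function(cn) {
    v <- lesions[[cn]]
    v <- v[is.finite(v)]
    if (!length(v))
      return(data.frame(metric = cn, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, stringsAsFactors = FALSE))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(metric = cn, n = length(v), median = q[2L], q1 = q[1L],
               q3 = q[3L], stringsAsFactors = FALSE)
  }))
}
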