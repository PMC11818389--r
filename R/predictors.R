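# Predictor analysis for RF application durations: normality and
# collinearity diagnostics, Breusch-Pagan heteroscedasticity, GAM per-term
# significance, and random-forest importances with a cross-validated
# reliability check.

duration_predictors <- c("cf_mean_g", "cf_start_g", "li_drop_ohm",
                         "li_start_ohm", "ild_mm")

#' Normality diagnostics
#'
#' Shapiro--Wilk and Anderson--Darling tests per column. Constant columns
#' are flagged as undefined rather than tested.
#'
#' @param data data frame of numeric columns (n >= 8 per column).
#' @return Data frame with per-column statistics and p-values and a
#'   `defined` flag.
#' @export
distribution_diagnostics <- function(data) {
  data <- as.data.frame(data)
  do.call(rbind, lapply(names(data), function(cn) {
    v <- data[[cn]]
    v <- v[is.finite(v)]
    if (length(v) < 8L)
      stop("distribution_diagnostics: need n >= 8 in column ", cn, call. = FALSE)
    if (stats::sd(v) == 0) {
      return(data.frame(variable = cn, n = length(v), defined = FALSE,
                        shapiro_w = NA_real_, shapiro_p = NA_real_,
                        ad_a = NA_real_, ad_p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sw <- stats::shapiro.test(if (length(v) > 5000) sample(v, 5000) else v)
    ad <- nortest::ad.test(v)
    data.frame(variable = cn, n = length(v), defined = TRUE,
               shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
               ad_a = unname(ad$statistic), ad_p = ad$p.value,
               stringsAsFactors = FALSE)
  }))
}

#' Collinearity diagnostics
#'
#' Variance inflation factors \eqn{VIF_j = 1/(1 - R^2_j)} from regressing
#' each predictor on the others, plus the Pearson correlation matrix.
#' Perfectly collinear predictors get an infinite VIF and a flag.
#'
#' @param design data frame or matrix of predictors (>= 2 columns,
#'   n > number of predictors).
#' @return List with `vif` (named vector), `correlations`, and
#'   `collinear` (logical vector of infinite-VIF predictors).
#' @export
collinearity_diagnostics <- function(design) {
  X <- as.matrix(as.data.frame(design))
  p <- ncol(X)
  if (p < 2L) stop("collinearity_diagnostics: need >= 2 predictors", call. = FALSE)
  if (nrow(X) <= p)
    stop("collinearity_diagnostics: need n > number of predictors", call. = FALSE)
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  list(vif = vif, correlations = stats::cor(X), collinear = !is.finite(vif))
}

#' Lagrange-multiplier (Breusch--Pagan) heteroscedasticity test
#'
#' Studentised Breusch--Pagan test, \eqn{LM = n R^2} from regressing the
#' squared residuals of the reference linear fit on the design; chi-square
#' with as many degrees of freedom as predictors.
#'
#' @param outcome numeric response.
#' @param design data frame/matrix of predictors for the reference linear
#'   fit.
#' @return List with `lm_statistic`, `df`, `p_value`.
#' @export
heteroscedasticity_lm <- function(outcome, design) {
  X <- as.data.frame(design)
  df <- data.frame(.y = outcome, X)
  fit <- stats::lm(.y ~ ., data = df)
  res_sd <- stats::sd(stats::residuals(fit))
  if (res_sd < 1e-10 * max(stats::sd(outcome), .Machine$double.eps))
    return(list(lm_statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                defined = FALSE))
  bp <- lmtest::bptest(fit, studentize = TRUE)
  list(lm_statistic = unname(bp$statistic), df = unname(bp$parameter),
       p_value = bp$p.value, defined = TRUE)
}

#' GAM of RF application duration on lesion covariates
#'
#' Additive model with one penalised thin-plate smooth per predictor,
#' smoothing parameters selected by REML; reports each smooth term's
#' approximate significance.
#'
#' @param lesions lesion-summary data frame (complete cases used).
#' @param outcome outcome column (e.g. `"duration_ai_s"`).
#' @param predictors predictor columns; defaults to the five lesion
#'   covariates (mean CF, start CF, LI drop, LI start, ILD).
#' @param k basis dimension per smooth (default 5; modest so small cohorts
#'   stay identifiable).
#' @return List with `term_p` (named p-values per smooth), `fit` (the
#'   `mgcv::gam` object), `n`, `r_squared`.
#' @export
fit_duration_gam <- function(lesions, outcome,
                             predictors = duration_predictors, k = 5) {
  dat <- lesions[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 10L * length(predictors))
    stop("fit_duration_gam: need n >= 10 per predictor", call. = FALSE)
  degenerate <- vapply(dat[predictors], function(v) stats::sd(v) == 0, TRUE)
  if (any(degenerate))
    stop("fit_duration_gam: constant predictor(s): ",
         paste(predictors[degenerate], collapse = ", "), call. = FALSE)
  form <- stats::as.formula(paste(
    outcome, "~", paste(sprintf("s(%s, k = %d)", predictors, k), collapse = " + ")))
  fit <- mgcv::gam(form, data = dat, method = "REML")
  st <- summary(fit)$s.table
  term_p <- st[, "p-value"]
  names(term_p) <- predictors
  list(term_p = term_p, fit = fit, n = n,
       r_squared = summary(fit)$r.sq)
}

#' Random-forest importance of duration predictors
#'
#' Impurity-based importances normalised to sum 1, from a random forest of
#' the duration outcome on the lesion covariates, with k-fold
#' cross-validated MSE and R2 as a reliability check: when the
#' cross-validated R2 falls below `reliability_r2` the importances are
#' flagged (and a warning raised) as unreliable, mirroring the caveat that
#' importances from a forest that does not predict well rank noise.
#'
#' @param lesions lesion-summary data frame (complete cases used).
#' @param outcome outcome column.
#' @param predictors predictor columns.
#' @param cv_folds folds for the CV reliability check (default 5).
#' @param seed integer seed.
#' @param num_trees forest size (default 500).
#' @param mtry candidate predictors per split; defaults to all of them, the
#'   regression convention of the stack these importances mirror.
#' @param reliability_r2 threshold below which the low-reliability warning
#'   fires (default 0.2).
#' @param importance `"impurity"` (default) or `"permutation"`.
#' @return List of class `importance_report`: `importance` (named, sums to
#'   1), `cv_mse`, `cv_r2`, `reliable`, `n`.
#' @export
rf_importance <- function(lesions, outcome, predictors = duration_predictors,
                          cv_folds = 5L, seed = 1L, num_trees = 500L,
                          mtry = length(predictors), reliability_r2 = 0.2,
                          importance = c("impurity", "permutation")) {
  importance <- match.arg(importance)
  mtry <- min(mtry, length(predictors))
  dat <- lesions[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < cv_folds) stop("rf_importance: fewer rows than folds", call. = FALSE)
  x <- dat[, predictors, drop = FALSE]
  y <- dat[[outcome]]
  set.seed(seed)
  fold <- sample(rep_len(seq_len(cv_folds), n))
  cv_pred <- numeric(n)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    m <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                        num.trees = num_trees, mtry = mtry,
                        num.threads = 1L, seed = seed + f)
    cv_pred[!tr] <- stats::predict(m, data = x[!tr, , drop = FALSE],
                                   num.threads = 1L)$predictions
  }
  cv_mse <- mean((y - cv_pred)^2)
  cv_r2 <- r2_score(y, cv_pred)
  full <- ranger::ranger(x = x, y = y, num.trees = num_trees, mtry = mtry,
                         importance = importance, num.threads = 1L,
                         seed = seed)
  imp <- full$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  reliable <- is.finite(cv_r2) && cv_r2 >= reliability_r2
  if (!reliable)
    warning(sprintf(paste0("rf_importance: cross-validated R2 = %.3f < %.2f; ",
                           "importances are unreliable"), cv_r2, reliability_r2))
  structure(list(importance = imp, cv_mse = cv_mse, cv_r2 = cv_r2,
                 reliable = reliable, n = n, outcome = outcome),
            class = "importance_report")
}

#' Full predictor analysis for one duration outcome
#'
#' Convenience wrapper running the diagnostics, GAM, and forest importance
#' for a given outcome, as reported for each stopping rule.
#'
#' @inheritParams rf_importance
#' @return List with `diagnostics` (normality + collinearity +
#'   heteroscedasticity), `gam`, `forest`.
#' @export
predictor_analysis <- function(lesions, outcome,
                               predictors = duration_predictors,
                               cv_folds = 5L, seed = 1L) {
  dat <- lesions[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  diags <- list(
    normality = distribution_diagnostics(dat),
    collinearity = collinearity_diagnostics(dat[, predictors, drop = FALSE]),
    heteroscedasticity = heteroscedasticity_lm(dat[[outcome]],
                                               dat[, predictors, drop = FALSE])
  )
  list(diagnostics = diags,
       gam = fit_duration_gam(dat, outcome, predictors),
       forest = rf_importance(dat, outcome, predictors, cv_folds, seed))
}
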