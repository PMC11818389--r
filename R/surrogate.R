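# Per-timepoint surrogate regressors for the lesion indices: training-table
# construction, quantile target transform, grid-searched cross-validated
# training (random forest / gradient boosting / ridge / lasso / elastic
# net), lesion-grouped holdout evaluation, and per-trace prediction.

ai_feature_cols  <- c("tau_s", "cf_g", "fti_gs", "power_w")
lsi_feature_cols <- c("tau_s", "cf_window6_g", "current_window6_ma", "power_w")

# per-timepoint feature block for a filtered uniform-grid trace
timepoint_features <- function(filtered, current_ma, tau_s) {
  data.frame(
    tau_s = tau_s,
    cf_g = filtered$cf_g,
    fti_gs = force_time_integral(filtered$cf_g, filtered$time_s),
    power_w = filtered$power_w,
    current_ma = current_ma,
    cf_window6_g = sliding_window_mean(filtered$cf_g, filtered$time_s, 6),
    current_window6_ma = sliding_window_mean(current_ma, filtered$time_s, 6)
  )
}

#' Build a per-timepoint training table
#'
#' Expands a list of raw traces into the per-timepoint rows the surrogate
#' models are trained on: each trace is resampled to the uniform grid,
#' LI-filtered, and every retained timepoint contributes its features and
#' the ground-truth index value from the reference formulas. Feature sets
#' mirror each formula's inputs — AI: elapsed time, CF, force--time integral
#' (Simpson), power; LSI: elapsed time, 6 s windowed CF and RF current,
#' power. `stride` subsamples the 997 Hz grid (default 10, i.e. ~100 rows
#' per second of ablation) preserving temporal order.
#'
#' @param traces list of raw `ablation_trace` objects.
#' @param constants list with `ai` and `lsi` constants (ground-truth
#'   oracle; see [calibrate_constants()]).
#' @param kind `"AI"` or `"LSI"`.
#' @param stride integer grid stride (>= 1).
#' @param fs_hz,window_s resampling rate and LI filter window.
#' @return A data frame with `lesion_id`, the feature columns, and the
#'   target column `index_value`; attribute `kind` records the index.
#' @export
build_training_table <- function(traces, constants, kind = c("AI", "LSI"),
                                 stride = 10L, fs_hz = 997, window_s = 1.5) {
  kind <- match.arg(kind)
  stride <- max(1L, as.integer(stride))
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    ft <- filter_li(resample_trace(traces[[i]], fs_hz), window_s)
    tau <- ft$time_s - ft$time_s[1L]
    cur <- rf_current(ft$power_w, ft$li_filtered_ohm)
    feats <- timepoint_features(ft, cur, tau)
    target <- if (kind == "AI") {
      ablation_index(ft$cf_g, ft$power_w, ft$time_s, constants$ai)
    } else {
      lesion_size_index(ft$cf_g, cur, ft$time_s, constants$lsi)
    }
    sub <- seq.int(1L, nrow(feats), by = stride)
    block <- feats[sub, , drop = FALSE]
    block$index_value <- target[sub]
    block$lesion_id <- ft$lesion_id[1L]
    rows[[i]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cols <- if (kind == "AI") ai_feature_cols else lsi_feature_cols
  out <- out[, c("lesion_id", cols, "index_value")]
  attr(out, "kind") <- kind
  attr(out, "feature_cols") <- cols
  out
}

#' Quantile transform of the training target
#'
#' Monotone map of the target to a standard-normal reference distribution
#' (rank-based, with linear interpolation between training quantiles), used
#' for the skewed LSI target. The returned object carries the forward and
#' inverse maps; the inverse is exact on training values up to interpolation
#' tolerance and clamps outside the training range.
#'
#' @param y numeric target vector (>= 10 distinct values).
#' @return An object of class `quantile_transform` with functions
#'   `transform(x)` and `inverse(z)`.
#' @export
quantile_transform_target <- function(y) {
  y <- y[is.finite(y)]
  ux <- sort(unique(y))
  if (length(ux) < 10L)
    stop("quantile_transform_target: need >= 10 distinct target values",
         call. = FALSE)
  # subsample the empirical quantile curve (scikit-style reference grid)
  n_q <- min(1000L, length(ux))
  probs <- seq(0, 1, length.out = n_q)
  qs <- stats::quantile(y, probs = probs, type = 7, names = FALSE)
  qs <- cummax(qs)                       # enforce monotonicity
  dup <- c(TRUE, diff(qs) > 0)
  qs <- qs[dup]; probs <- probs[dup]
  eps <- 1e-7
  transform <- function(x) {
    p <- stats::approx(qs, probs, xout = x, rule = 2, ties = "ordered")$y
    stats::qnorm(pmin(pmax(p, eps), 1 - eps))
  }
  inverse <- function(z) {
    p <- stats::pnorm(z)
    stats::approx(probs, qs, xout = pmin(pmax(p, eps), 1 - eps),
                  rule = 2, ties = "ordered")$y
  }
  structure(list(transform = transform, inverse = inverse,
                 range = range(y)), class = "quantile_transform")
}

# ---- model family backends ---------------------------------------------

# glmnet requires >= 2 predictor columns; pad single-feature designs with a
# zero column that cannot influence the fit
glmnet_matrix <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) == 1L) m <- cbind(m, `..pad..` = 0)
  m
}

fit_family <- function(family, x, y, pars, seed) {
  set.seed(seed)
  switch(family,
    random_forest = ranger::ranger(
      x = x, y = y,
      num.trees = pars$num_trees %||% 100L,
      mtry = min(ncol(x), pars$mtry %||% max(1L, floor(ncol(x) / 3))),
      min.node.size = pars$min_node_size %||% 5L,
      num.threads = 1L, seed = seed, verbose = FALSE,
      respect.unordered.factors = FALSE),
    gradient_boosting = xgboost::xgb.train(
      params = list(eta = pars$eta %||% 0.1,
                    max_depth = pars$max_depth %||% 6L,
                    subsample = 1, nthread = 1L, seed = seed,
                    objective = "reg:squarederror"),
      data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1L),
      nrounds = pars$nrounds %||% 150L, verbose = 0),
    ridge = glmnet::glmnet(glmnet_matrix(x), y, alpha = 0,
                           lambda = pars$lambda %||% 0.01),
    lasso = glmnet::glmnet(glmnet_matrix(x), y, alpha = 1,
                           lambda = pars$lambda %||% 0.01),
    elastic_net = glmnet::glmnet(glmnet_matrix(x), y,
                                 alpha = pars$alpha %||% 0.5,
                                 lambda = pars$lambda %||% 0.01),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

predict_family <- function(family, model, x) {
  switch(family,
    random_forest = stats::predict(model, data = x,
                                   num.threads = 1L)$predictions,
    gradient_boosting = stats::predict(model, as.matrix(x)),
    # glmnet families
    as.numeric(stats::predict(model, newx = glmnet_matrix(x)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_grid <- function(family) {
  switch(family,
    random_forest = list(num_trees = c(100L), mtry = c(2L, 3L),
                         min_node_size = c(5L)),
    gradient_boosting = list(nrounds = c(150L), eta = c(0.1),
                             max_depth = c(4L, 6L)),
    list(lambda = c(0.001, 0.01, 0.1, 1))
  )
}

# deterministic lesion-grouped fold assignment
grouped_folds <- function(lesion_id, k, seed) {
  groups <- unique(lesion_id)
  set.seed(seed)
  fold_of_group <- sample(rep_len(seq_len(k), length(groups)))
  names(fold_of_group) <- groups
  unname(fold_of_group[lesion_id])
}

r2_score <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - ss_res / ss_tot
}

#' Grid-search cross-validated training of a surrogate model
#'
#' Exhaustive search over a hyperparameter grid, scored by k-fold
#' cross-validated R2 with lesion-grouped folds (all timepoints of a lesion
#' stay in one fold, so near-duplicate neighbouring rows cannot leak across
#' the split); the best configuration is refit on the full table. The LSI
#' target is optionally passed through [quantile_transform_target()] before
#' fitting; predictions are back-transformed everywhere downstream.
#'
#' @param table a training table from [build_training_table()].
#' @param family one of `"random_forest"`, `"gradient_boosting"`,
#'   `"ridge"`, `"lasso"`, `"elastic_net"`.
#' @param grid named list of hyperparameter value vectors (crossed
#'   exhaustively); `NULL` uses a small per-family default.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed (folds and fits are deterministic given it).
#' @param transform_target apply the quantile transform to the target
#'   before fitting (the LSI convention).
#' @param group_folds lesion-grouped folds (default) or row-level folds.
#' @return An object of class `surrogate_fit`: the refit model, family,
#'   chosen hyperparameters, CV table, feature columns, optional transform,
#'   and training ranges for the extrapolation guard.
#' @export
tune_and_train <- function(table, family = "random_forest", grid = NULL,
                           folds = 10L, seed = 1L, transform_target = FALSE,
                           group_folds = TRUE) {
  feature_cols <- attr(table, "feature_cols") %||%
    setdiff(names(table), c("lesion_id", "index_value"))
  if (nrow(table) < folds)
    stop("tune_and_train: fewer rows than folds", call. = FALSE)
  y_raw <- table$index_value
  if (length(unique(y_raw)) < 2L)
    stop("tune_and_train: degenerate single-value target", call. = FALSE)
  if (is.null(grid)) grid <- default_grid(family)
  configs <- expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(configs) == 0L) stop("tune_and_train: empty grid", call. = FALSE)

  qt <- NULL
  y <- y_raw
  if (transform_target) {
    qt <- quantile_transform_target(y_raw)
    y <- qt$transform(y_raw)
  }
  x <- table[, feature_cols, drop = FALSE]
  fold_id <- if (group_folds) grouped_folds(table$lesion_id, folds, seed)
             else { set.seed(seed); sample(rep_len(seq_len(folds), nrow(table))) }

  if (nrow(configs) == 1L) {
    # a single configuration needs no model selection: direct fit
    best_pars <- as.list(configs[1L, , drop = FALSE])
    model <- fit_family(family, x, y, best_pars, seed)
    return(structure(list(
      family = family, model = model, hyperparameters = best_pars,
      cv = data.frame(configs, cv_r2 = NA_real_),
      feature_cols = feature_cols, transform = qt,
      feature_ranges = lapply(x, range), seed = seed, folds = folds,
      kind = attr(table, "kind")
    ), class = "surrogate_fit"))
  }

  cv_scores <- numeric(nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    pars <- as.list(configs[ci, , drop = FALSE])
    scores <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (!any(tr) || !any(!tr)) return(NA_real_)
      m <- fit_family(family, x[tr, , drop = FALSE], y[tr], pars, seed + f)
      pred <- predict_family(family, m, x[!tr, , drop = FALSE])
      obs_raw <- y_raw[!tr]
      pred_raw <- if (is.null(qt)) pred else qt$inverse(pred)
      r2_score(obs_raw, pred_raw)
    }, numeric(1))
    cv_scores[ci] <- mean(scores, na.rm = TRUE)
  }
  best <- which.max(cv_scores)
  best_pars <- as.list(configs[best, , drop = FALSE])
  model <- fit_family(family, x, y, best_pars, seed)
  structure(list(
    family = family, model = model, hyperparameters = best_pars,
    cv = data.frame(configs, cv_r2 = cv_scores),
    feature_cols = feature_cols, transform = qt,
    feature_ranges = lapply(x, range), seed = seed, folds = folds,
    kind = attr(table, "kind")
  ), class = "surrogate_fit")
}

#' Lesion-grouped holdout evaluation
#'
#' Splits the table into lesion-grouped train/holdout partitions
#' (`holdout_fraction` of lesions, default 30%), refits the supplied fit's
#' family and hyperparameters on the training partition, and reports holdout
#' R2 and MAE on back-transformed predictions.
#'
#' @param fit a `surrogate_fit` (its family/hyperparameters/transform are
#'   reused; the model itself is refit on the training partition).
#' @param table the training table.
#' @param holdout_fraction fraction of lesions held out (default 0.3).
#' @param seed split seed.
#' @return A list: `r2`, `mae`, `n_holdout_rows`, `holdout_lesions`, and the
#'   refit `fit` (class `surrogate_fit`) trained without the holdout.
#' @export
evaluate_holdout <- function(fit, table, holdout_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(fit, "surrogate_fit"))
  if (holdout_fraction <= 0 || holdout_fraction >= 1)
    stop("evaluate_holdout: holdout_fraction must be in (0, 1)", call. = FALSE)
  lesions <- unique(table$lesion_id)
  set.seed(seed)
  n_hold <- max(1L, round(holdout_fraction * length(lesions)))
  hold <- sample(lesions, n_hold)
  if (length(hold) < 2L)
    warning("evaluate_holdout: holdout contains a single lesion; metrics unstable")
  is_hold <- table$lesion_id %in% hold
  train_tab <- table[!is_hold, , drop = FALSE]
  attr(train_tab, "feature_cols") <- fit$feature_cols
  attr(train_tab, "kind") <- fit$kind

  y_train <- train_tab$index_value
  qt <- if (is.null(fit$transform)) NULL else quantile_transform_target(y_train)
  y_fit <- if (is.null(qt)) y_train else qt$transform(y_train)
  x_train <- train_tab[, fit$feature_cols, drop = FALSE]
  model <- fit_family(fit$family, x_train, y_fit, fit$hyperparameters, seed)
  refit <- fit
  refit$model <- model
  refit$transform <- qt
  refit$feature_ranges <- lapply(x_train, range)

  x_hold <- table[is_hold, fit$feature_cols, drop = FALSE]
  pred <- predict_family(fit$family, model, x_hold)
  if (!is.null(qt)) pred <- qt$inverse(pred)
  obs <- table$index_value[is_hold]
  list(r2 = r2_score(obs, pred), mae = mean(abs(obs - pred)),
       n_holdout_rows = sum(is_hold), holdout_lesions = hold, fit = refit)
}

#' Predict an index series from trace features
#'
#' Applies a trained surrogate to per-timepoint features, back-transforming
#' through the quantile map when one was used. Feature values outside a
#' two-sided 1% extension of the training ranges are flagged (attribute
#' `extrapolated`), not rejected. An optional isotonic post-pass enforces a
#' non-decreasing series.
#'
#' @param fit a `surrogate_fit`.
#' @param features data frame containing the fit's feature columns (e.g.
#'   from [build_training_table()] on a new trace).
#' @param monotone enforce a non-decreasing prediction series via isotonic
#'   regression (default `FALSE`).
#' @return Numeric predictions with logical attribute `extrapolated`.
#' @export
predict_index_series <- function(fit, features, monotone = FALSE) {
  stopifnot(inherits(fit, "surrogate_fit"))
  missing_cols <- setdiff(fit$feature_cols, names(features))
  if (length(missing_cols))
    stop("predict_index_series: missing feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- features[, fit$feature_cols, drop = FALSE]
  flag <- rep(FALSE, nrow(x))
  for (cn in fit$feature_cols) {
    r <- fit$feature_ranges[[cn]]
    pad <- 0.01 * max(diff(r), .Machine$double.eps)
    flag <- flag | x[[cn]] < r[1L] - pad | x[[cn]] > r[2L] + pad
  }
  pred <- predict_family(fit$family, fit$model, x)
  if (!is.null(fit$transform)) pred <- fit$transform$inverse(pred)
  if (monotone && length(pred) > 1L)
    pred <- cummax(stats::isoreg(pred)$yf)  # cummax cleans pool round-off
  attr(pred, "extrapolated") <- flag
  pred
}
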