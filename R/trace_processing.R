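# Raw trace -> analysis time base: 997 Hz linear resampling, 1.5 s
# moving-mean LI filtering with left-edge trim, LI-drop plateau detection,
# time-to-target extraction, tip geometry, and per-lesion summaries.

#' Resample a raw trace onto a uniform grid
#'
#' Linearly interpolates every channel onto the grid
#' `t0, t0 + 1/fs, ...` within the raw time span (no extrapolation).
#' 997 Hz is the mapping-system export rate the downstream stages assume.
#'
#' @param trace an `ablation_trace` data frame (see [simulate_trace()] or
#'   [read_trace_table()]).
#' @param fs_hz target sampling frequency, Hz (default 997).
#' @return The trace on the uniform grid, class `ablation_trace`, with
#'   attribute `fs_hz` set.
#' @export
resample_trace <- function(trace, fs_hz = 997) {
  t <- trace$time_s
  if (length(t) < 2L)
    stop("resample_trace: need at least 2 raw samples", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("resample_trace: raw times must be strictly increasing", call. = FALSE)
  grid <- seq(t[1L], t[length(t)], by = 1 / fs_hz)
  interp <- function(y) stats::approx(t, y, xout = grid, method = "linear")$y
  out <- data.frame(
    procedure_id = trace$procedure_id[1L], lesion_id = trace$lesion_id[1L],
    time_s = grid,
    cf_g = interp(trace$cf_g), power_w = interp(trace$power_w),
    li_ohm = interp(trace$li_ohm),
    x_mm = interp(trace$x_mm), y_mm = interp(trace$y_mm),
    z_mm = interp(trace$z_mm),
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- attr(trace, "params")
  attr(out, "fs_hz") <- fs_hz
  class(out) <- c("ablation_trace", "data.frame")
  out
}

# centered moving mean with shrinking windows at both edges, O(n) via cumsum
centered_moving_mean <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Filter the local-impedance channel
#'
#' Centered moving-mean filter of the LI channel (window `window_s`, sample
#' count forced odd for symmetry). The left edge — the first half-window,
#' where the filter extends over the initial data points and its support is
#' incomplete — is trimmed from the output; the right edge keeps
#' shrinking-window means so a plateau near the trace end stays defined. A
#' trailing (causal) variant is available via `align = "trailing"`.
#'
#' @param trace a uniform-grid trace from [resample_trace()].
#' @param window_s filter window length, s (default 1.5).
#' @param align `"centered"` (default) or `"trailing"`.
#' @return The trace restricted to the trimmed support with an extra
#'   `li_filtered_ohm` column; attributes `trim_offset_s` (duration removed
#'   at the left edge) and `filter_window_s`.
#' @export
filter_li <- function(trace, window_s = 1.5, align = c("centered", "trailing")) {
  align <- match.arg(align)
  fs <- attr(trace, "fs_hz")
  if (is.null(fs)) {
    h <- check_uniform_grid(trace$time_s, "filter_li")
    fs <- 1 / h
  }
  n <- nrow(trace)
  dur <- trace$time_s[n] - trace$time_s[1L]
  if (dur <= window_s)
    stop("filter_li: trace duration must exceed the filter window", call. = FALSE)
  w <- round(window_s * fs)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  if (align == "centered") {
    filt <- centered_moving_mean(trace$li_ohm, half)
    keep <- if (half > 0L) seq.int(half + 1L, n) else seq_len(n)
  } else {
    filt <- sliding_window_mean(trace$li_ohm, trace$time_s, window_s)
    keep <- seq.int(min(w, n), n)
  }
  trim_offset <- trace$time_s[keep[1L]] - trace$time_s[1L]
  out <- trace[keep, , drop = FALSE]
  out$li_filtered_ohm <- filt[keep]
  rownames(out) <- NULL
  attr(out, "params") <- attr(trace, "params")
  attr(out, "fs_hz") <- fs
  attr(out, "trim_offset_s") <- trim_offset
  attr(out, "filter_window_s") <- window_s
  class(out) <- c("filtered_trace", "ablation_trace", "data.frame")
  out
}

#' Detect the LI-drop plateau
#'
#' The plateau is the minimum of the filtered LI over the lesion: for a
#' drop-then-rebound trace this is the curve's single interior local
#' minimum, found deterministically as the global minimum (first sample on
#' ties). If the minimum falls on the final sample the LI never rebounded
#' within the trace and a `no_rebound` flag is set in place of a chart
#' reviewer's visual confirmation. A strict local-minimum detector
#' with a prominence threshold is available via `method = "local"`.
#'
#' @param filtered a `filtered_trace` from [filter_li()].
#' @param method `"global"` (default) or `"local"`.
#' @param prominence_ohm minimum depth (ohm) below both flanking maxima for
#'   `method = "local"`.
#' @return A list of class `plateau_result`: `t_plateau_s` (seconds from
#'   ablation start), `li_at_plateau_ohm`, `li_start_ohm` (first filtered
#'   sample after the trim), `li_drop_ohm`, and `no_rebound`.
#' @export
detect_plateau <- function(filtered, method = c("global", "local"),
                           prominence_ohm = 1) {
  method <- match.arg(method)
  li <- filtered$li_filtered_ohm
  if (is.null(li) || length(li) == 0L)
    stop("detect_plateau: filtered LI series is empty", call. = FALSE)
  n <- length(li)
  if (method == "global") {
    idx <- which.min(li)
  } else {
    # strict interior local minima with the required prominence
    cand <- which(diff(sign(diff(li))) > 0) + 1L
    if (length(cand)) {
      prom <- vapply(cand, function(i) {
        left <- max(li[seq_len(i)])
        right <- max(li[seq.int(i, n)])
        min(left, right) - li[i]
      }, numeric(1))
      cand <- cand[prom >= prominence_ohm]
    }
    idx <- if (length(cand)) cand[which.min(li[cand])] else which.min(li)
  }
  li_start <- li[1L]
  structure(list(
    t_plateau_s = filtered$time_s[idx],
    li_at_plateau_ohm = li[idx],
    li_start_ohm = li_start,
    li_drop_ohm = max(0, li_start - li[idx]),
    no_rebound = idx == n
  ), class = "plateau_result")
}

#' First time an index series reaches its target
#'
#' Returns the first grid time at which the series value is `>= target`
#' (no interpolation between grid points; at 997 Hz the induced error is at
#' most one grid step, ~1 ms), or `NA` if the target is never reached
#' within the trace — the censoring that produces missing LSI durations
#' downstream.
#'
#' @param time_s time grid, s; durations are measured from `time_s[1]`.
#' @param values index series aligned to `time_s`.
#' @param target positive target value (400 for AI, 4 for LSI).
#' @return Duration in seconds, or `NA_real_`.
#' @export
time_to_target <- function(time_s, values, target) {
  if (target <= 0) stop("time_to_target: target must be > 0", call. = FALSE)
  if (length(values) == 0L)
    stop("time_to_target: empty series", call. = FALSE)
  hit <- which(values >= target)
  if (length(hit) == 0L) return(NA_real_)
  time_s[hit[1L]] - time_s[1L]
}

#' Mean catheter-tip position of a lesion
#'
#' @param trace an `ablation_trace` (raw or resampled).
#' @return Length-3 numeric `(x, y, z)` in mm.
#' @export
mean_tip_position <- function(trace) {
  if (nrow(trace) == 0L)
    stop("mean_tip_position: empty trace", call. = FALSE)
  c(x = mean(trace$x_mm), y = mean(trace$y_mm), z = mean(trace$z_mm))
}

#' Interlesion distances within procedures
#'
#' For each lesion, the Euclidean distance from its mean tip position to the
#' nearest other lesion's mean position in the same procedure (1-nearest
#' neighbour, self excluded) — the spatial reading of "adjacent". A
#' temporal-predecessor variant (distance to the previous lesion in table
#' order) is available via `method = "predecessor"`. Lesions in singleton
#' procedures get `NA`.
#'
#' @param positions data frame with columns `procedure_id`, `lesion_id`,
#'   `x_mm`, `y_mm`, `z_mm` (one row per lesion; see [mean_tip_position()]).
#' @param method `"nearest"` (default) or `"predecessor"`.
#' @return Numeric vector of ILDs (mm) aligned to the rows of `positions`.
#' @export
interlesion_distance <- function(positions, method = c("nearest", "predecessor")) {
  method <- match.arg(method)
  ild <- rep(NA_real_, nrow(positions))
  for (pid in unique(positions$procedure_id)) {
    rows <- which(positions$procedure_id == pid)
    if (length(rows) < 2L) next
    xyz <- as.matrix(positions[rows, c("x_mm", "y_mm", "z_mm")])
    if (method == "nearest") {
      d <- as.matrix(stats::dist(xyz))
      diag(d) <- Inf
      ild[rows] <- apply(d, 1L, min)
    } else {
      step <- sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                              xyz[-nrow(xyz), , drop = FALSE])^2))
      ild[rows] <- c(NA_real_, step)
    }
  }
  ild
}

#' Summarise one lesion
#'
#' Assembles the per-lesion record used by the cohort comparison: durations
#' to the AI and LSI targets and to the LI plateau, LI start/drop, mean and
#' starting contact force, and the index values read off at the plateau.
#' "Start CF" is the mean CF over the first second of the (trimmed) trace —
#' a single first sample would be noise-dominated.
#'
#' @param filtered a `filtered_trace` from [filter_li()].
#' @param plateau a `plateau_result` from [detect_plateau()].
#' @param ai_series AI values aligned to `filtered$time_s`.
#' @param lsi_series LSI values aligned to `filtered$time_s`.
#' @param ai_target,lsi_target index targets (defaults 400 and 4).
#' @return One-row data frame (lesion-summary schema); `ild_mm` is filled
#'   in later by [process_cohort()].
#' @export
summarize_lesion <- function(filtered, plateau, ai_series, lsi_series,
                             ai_target = 400, lsi_target = 4) {
  stopifnot(inherits(plateau, "plateau_result"))
  n <- nrow(filtered)
  if (length(ai_series) != n || length(lsi_series) != n)
    stop("summarize_lesion: index series must align with the filtered grid",
         call. = FALSE)
  t <- filtered$time_s
  idx_plateau <- which.min(abs(t - plateau$t_plateau_s))
  first_second <- t <= t[1L] + 1
  data.frame(
    procedure_id = filtered$procedure_id[1L],
    lesion_id = filtered$lesion_id[1L],
    duration_li_s = plateau$t_plateau_s - t[1L],
    duration_ai_s = time_to_target(t, ai_series, ai_target),
    duration_lsi_s = time_to_target(t, lsi_series, lsi_target),
    li_start_ohm = plateau$li_start_ohm,
    li_drop_ohm = plateau$li_drop_ohm,
    cf_mean_g = mean(filtered$cf_g),
    cf_start_g = mean(filtered$cf_g[first_second]),
    ai_at_plateau = ai_series[idx_plateau],
    lsi_at_plateau = lsi_series[idx_plateau],
    no_rebound = plateau$no_rebound,
    ild_mm = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Process a cohort of raw traces into a lesion table
#'
#' Runs the full per-lesion pipeline — resample to the uniform grid, filter
#' LI, detect the plateau, compute (or predict) AI and LSI series, extract
#' durations — and attaches interlesion distances from the mean tip
#' positions. Index series come either from the reference formulas with the
#' supplied `constants` (ground-truth path) or from trained surrogate fits
#' (`ai_fit` / `lsi_fit`; see [predict_index_series()]).
#'
#' @param traces list of raw `ablation_trace` objects.
#' @param constants list with `ai` and `lsi` constants
#'   (see [calibrate_constants()]); used when fits are not given.
#' @param ai_fit,lsi_fit optional `surrogate_fit` objects used instead of
#'   the formulas.
#' @param fs_hz resampling rate, Hz.
#' @param window_s LI filter window, s.
#' @param ai_target,lsi_target index targets.
#' @param predict_stride grid stride for surrogate prediction (predicting at
#'   every 997 Hz sample is needless; durations move by at most
#'   `stride / fs` s).
#' @return A lesion-summary data frame, one row per lesion.
#' @export
process_cohort <- function(traces, constants = NULL, ai_fit = NULL,
                           lsi_fit = NULL, fs_hz = 997, window_s = 1.5,
                           ai_target = 400, lsi_target = 4,
                           predict_stride = 10L) {
  if (is.null(constants) && (is.null(ai_fit) || is.null(lsi_fit)))
    stop("process_cohort: supply constants or both surrogate fits", call. = FALSE)
  rows <- vector("list", length(traces))
  pos <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- resample_trace(traces[[i]], fs_hz)
    ft <- filter_li(tr, window_s)
    pl <- detect_plateau(ft)
    tau <- ft$time_s - ft$time_s[1L]
    cur <- rf_current(ft$power_w, ft$li_filtered_ohm)
    if (!is.null(ai_fit) && !is.null(lsi_fit)) {
      sub <- seq.int(1L, nrow(ft), by = predict_stride)
      feats <- timepoint_features(ft, cur, tau)
      ai_s <- stats::approx(tau[sub],
                            predict_index_series(ai_fit, feats[sub, ]),
                            xout = tau, rule = 2)$y
      lsi_s <- stats::approx(tau[sub],
                             predict_index_series(lsi_fit, feats[sub, ]),
                             xout = tau, rule = 2)$y
    } else {
      ai_s <- ablation_index(ft$cf_g, ft$power_w, ft$time_s, constants$ai)
      lsi_s <- lesion_size_index(ft$cf_g, cur, ft$time_s, constants$lsi)
    }
    rows[[i]] <- summarize_lesion(ft, pl, ai_s, lsi_s, ai_target, lsi_target)
    mp <- mean_tip_position(tr)
    pos[[i]] <- data.frame(procedure_id = tr$procedure_id[1L],
                           lesion_id = tr$lesion_id[1L],
                           x_mm = mp[["x"]], y_mm = mp[["y"]], z_mm = mp[["z"]],
                           stringsAsFactors = FALSE)
  }
  lesions <- do.call(rbind, rows)
  positions <- do.call(rbind, pos)
  lesions$ild_mm <- interlesion_distance(positions)
  rownames(lesions) <- NULL
  lesions
}
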