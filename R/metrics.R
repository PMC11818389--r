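# Reference (oracle) implementations of the lesion-index formulas and the
# numerical primitives they need: cumulative Simpson integration, Ohm's-law
# RF current, and trailing sliding-window means.

check_uniform_grid <- function(time_s, what = "series") {
  if (length(time_s) < 2L)
    stop(sprintf("%s: need at least 2 samples", what), call. = FALSE)
  dt <- diff(time_s)
  if (any(dt <= 0))
    stop(sprintf("%s: time grid must be strictly increasing", what), call. = FALSE)
  h <- dt[1L]
  if (max(abs(dt - h)) > 1e-6 * h)
    stop(sprintf("%s: time grid must be uniform (resample first)", what),
         call. = FALSE)
  h
}

#' Cumulative force--time integral by Simpson's rule
#'
#' Computes the running integral \eqn{FTI(\tau) = \int_0^\tau CF(s) ds}
#' (g·s) at every grid point of a uniformly sampled contact-force series.
#' Even-offset points use composite Simpson; odd-offset points use the
#' cubic-exact 4-point Newton--Cotes correction for the trailing interval, so
#' the cumulative integral is exact to round-off for polynomial integrands of
#' degree <= 3 (degree <= 2 when fewer than 4 samples are available).
#'
#' @param cf contact-force samples, g (any non-negative integrand works; the
#'   same routine integrates the AI integrand).
#' @param time_s uniform time grid, s.
#' @return Numeric vector of the same length: the cumulative integral, with
#'   value 0 at the first sample.
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' tail(force_time_integral(rep(10, length(t)), t), 1) # 50 g·s
#' @export
force_time_integral <- function(cf, time_s) {
  if (length(cf) != length(time_s))
    stop("force_time_integral: cf and time_s lengths differ", call. = FALSE)
  h <- check_uniform_grid(time_s, "force_time_integral")
  n <- length(cf)
  if (any(!is.finite(cf)))
    stop("force_time_integral: non-finite integrand", call. = FALSE)
  out <- numeric(n)
  if (n == 2L) {
    out[2L] <- h * (cf[1L] + cf[2L]) / 2
    return(out)
  }
  # increments over each interval [i-1, i]
  inc <- numeric(n - 1L)
  if (n >= 4L) {
    # interior intervals: cubic through the 4 nearest points
    # first interval: points 1..4, integrate over [t1, t2]
    inc[1L] <- h / 24 * (9 * cf[1L] + 19 * cf[2L] - 5 * cf[3L] + cf[4L])
    # middle intervals [i, i+1] for i = 2..n-2: points i-1..i+2
    if (n >= 4L) {
      i <- 2:(n - 2L)
      inc[i] <- h / 24 * (-cf[i - 1L] + 13 * cf[i] + 13 * cf[i + 1L] - cf[i + 2L])
    }
    # last interval: points n-3..n, integrate over [t_{n-1}, t_n]
    inc[n - 1L] <- h / 24 * (cf[n - 3L] - 5 * cf[n - 2L] + 19 * cf[n - 1L] + 9 * cf[n])
  } else { # n == 3: quadratic through the 3 points
    inc[1L] <- h / 12 * (5 * cf[1L] + 8 * cf[2L] - cf[3L])
    inc[2L] <- h / 12 * (-cf[1L] + 8 * cf[2L] + 5 * cf[3L])
  }
  out[-1L] <- cumsum(inc)
  out
}

#' RF current from power and local impedance
#'
#' Ohm's-law analogue for alternating current: \eqn{I = \sqrt{P/Z}},
#' returned in mA.
#'
#' @param power_w delivered power, W (>= 0).
#' @param li_ohm local impedance, ohm (> 0).
#' @return Current in mA (vectorised).
#' @examples
#' rf_current(40, 160) # 500 mA
#' @export
rf_current <- function(power_w, li_ohm) {
  if (any(!is.finite(power_w)) || any(!is.finite(li_ohm)))
    stop("rf_current: non-finite inputs", call. = FALSE)
  if (any(li_ohm <= 0)) stop("rf_current: impedance must be > 0", call. = FALSE)
  if (any(power_w < 0)) stop("rf_current: power must be >= 0", call. = FALSE)
  1000 * sqrt(power_w / li_ohm)
}

#' Trailing sliding-window mean
#'
#' Mean of a series over the trailing `window_s` seconds at every grid point,
#' with the window truncated at the start of the trace (the first samples
#' average over `min(t - t0 + dt, window_s)` seconds). Used for the 6 s
#' windowed contact-force and current inputs of the LSI formula.
#'
#' @param x numeric series.
#' @param time_s uniform time grid, s.
#' @param window_s window length, s (default 6).
#' @return Windowed-mean series of the same length.
#' @export
sliding_window_mean <- function(x, time_s, window_s = 6) {
  if (window_s <= 0) stop("sliding_window_mean: window_s must be > 0", call. = FALSE)
  h <- check_uniform_grid(time_s, "sliding_window_mean")
  n <- length(x)
  if (length(time_s) != n)
    stop("sliding_window_mean: length mismatch", call. = FALSE)
  w <- max(1L, min(n, round(window_s / h)))
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(0L, i - w)            # cumulative sum index just before window
  counts <- i - lo
  (cs - c(0, cs)[lo + 1L]) / counts
}

#' Ablation Index series
#'
#' Evaluates \eqn{AI(\tau) = K (\int_0^\tau CF^a P^b ds)^c} on a uniform
#' grid; the integral uses [force_time_integral()]'s cumulative Simpson rule.
#' The series is non-decreasing for non-negative inputs and starts at 0.
#'
#' @param cf contact-force series, g (>= 0).
#' @param power power series, W (>= 0).
#' @param time_s uniform time grid, s.
#' @param constants an [ai_constants()] object.
#' @return Numeric AI series aligned to `time_s`.
#' @export
ablation_index <- function(cf, power, time_s, constants) {
  stopifnot(inherits(constants, "ai_constants"))
  if (any(cf < 0) || any(power < 0))
    stop("ablation_index: CF and power must be >= 0", call. = FALSE)
  integrand <- cf^constants$a * power^constants$b
  integral <- force_time_integral(integrand, time_s)
  integral[integral < 0] <- 0  # guard round-off at the left edge
  constants$K * integral^constants$c
}

#' Lesion Size Index series
#'
#' Evaluates the LSI formula on a uniform grid:
#' a saturating force term plus a saturating squared-current term, scaled by
#' a time factor normalised to 1 at 60 s (see [lsi_constants()]). `F` and `I`
#' are the 6 s trailing-window means of contact force and RF current,
#' computed internally via [sliding_window_mean()].
#'
#' @param cf contact-force series, g (>= 0).
#' @param current_ma RF current series, mA (>= 0).
#' @param time_s uniform time grid, s; `tau` is measured from the first
#'   sample.
#' @param constants an [lsi_constants()] object.
#' @param window_s averaging window for F and I, s (default 6).
#' @return Numeric LSI series aligned to `time_s`.
#' @export
lesion_size_index <- function(cf, current_ma, time_s, constants, window_s = 6) {
  stopifnot(inherits(constants, "lsi_constants"))
  if (any(cf < 0) || any(current_ma < 0))
    stop("lesion_size_index: CF and current must be >= 0", call. = FALSE)
  Fw <- sliding_window_mean(cf, time_s, window_s)
  Iw <- sliding_window_mean(current_ma, time_s, window_s)
  lsi_pointwise(Fw, Iw, time_s - time_s[1L], constants)
}

#' Pointwise LSI evaluation from windowed inputs
#'
#' The bare formula, exposed separately so tests can compare the series
#' implementation against a literal transcription, and so calibration can
#' evaluate it at reference levels.
#'
#' @param f_g windowed contact force, g.
#' @param i_ma windowed RF current, mA.
#' @param tau_s elapsed time, s.
#' @param constants an [lsi_constants()] object.
#' @return LSI value(s).
#' @export
lsi_pointwise <- function(f_g, i_ma, tau_s, constants) {
  cc <- constants
  sat <- cc$b0 * (1 - exp(-f_g / cc$b1)) + cc$b2 * (1 - exp(-i_ma^2 / cc$b3))
  tf <- (1 - cc$b4) + cc$b4 * (1 - exp(-tau_s / cc$b5)) / (1 - exp(-60 / cc$b5))
  sat * tf
}
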