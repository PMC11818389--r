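#' Ablation Index constants
#'
#' Bundles the four coefficients of the Ablation Index (AI) formula
#' \deqn{AI(\tau) = K \left( \int_0^\tau CF(s)^a \, P(s)^b \, ds \right)^c}
#' where CF is contact force (g) and P is delivered power (W). The
#' manufacturer's coefficients are proprietary; these are configurable
#' stand-ins, typically produced by [calibrate_constants()].
#'
#' @param K positive scale factor (arbitrary index units).
#' @param a contact-force exponent (dimensionless, >= 0).
#' @param b power exponent (dimensionless, >= 0).
#' @param c outer exponent applied to the integral (> 0).
#' @return An object of class `ai_constants`.
#' @seealso [ablation_index()], [calibrate_constants()]
#' @export
ai_constants <- function(K, a, b, c) {
  stopifnot(is.numeric(K), is.numeric(a), is.numeric(b), is.numeric(c))
  if (K <= 0) stop("ai_constants: K must be > 0", call. = FALSE)
  if (c <= 0) stop("ai_constants: c must be > 0", call. = FALSE)
  if (a < 0) stop("ai_constants: a must be >= 0", call. = FALSE)
  if (b < 0) stop("ai_constants: b must be >= 0", call. = FALSE)
  structure(list(K = K, a = a, b = b, c = c), class = "ai_constants")
}

#' Lesion Size Index constants
#'
#' Bundles the six coefficients of the Lesion Size Index (LSI) formula
#' \deqn{LSI(\tau) = \left[ b_0 (1 - e^{-F/b_1}) + b_2 (1 - e^{-I^2/b_3}) \right]
#'   \left[ (1 - b_4) + b_4 \frac{1 - e^{-\tau/b_5}}{1 - e^{-60/b_5}} \right]}
#' where F and I are 6 s trailing-window means of contact force (g) and RF
#' current (mA). The time factor is normalised so it equals 1 at
#' \eqn{\tau = 60} s. Proprietary in the real device; configurable stand-ins
#' here.
#'
#' @param b0 force-term scale (index units, >= 0).
#' @param b1 force e-folding constant (g, > 0).
#' @param b2 current-term scale (index units, >= 0).
#' @param b3 squared-current e-folding constant (mA^2, > 0).
#' @param b4 time-mixing weight in \[0, 1\].
#' @param b5 time e-folding constant (s, > 0).
#' @return An object of class `lsi_constants`.
#' @seealso [lesion_size_index()], [calibrate_constants()]
#' @export
lsi_constants <- function(b0, b1, b2, b3, b4, b5) {
  vals <- c(b0 = b0, b1 = b1, b2 = b2, b3 = b3, b4 = b4, b5 = b5)
  if (any(!is.finite(vals))) stop("lsi_constants: all constants must be finite", call. = FALSE)
  if (b1 <= 0 || b3 <= 0 || b5 <= 0)
    stop("lsi_constants: b1, b3, b5 must be > 0", call. = FALSE)
  if (b4 < 0 || b4 > 1) stop("lsi_constants: b4 must lie in [0, 1]", call. = FALSE)
  if (b0 < 0 || b2 < 0) stop("lsi_constants: b0, b2 must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "lsi_constants")
}

#' Calibrate stand-in index constants to target crossing times
#'
#' Solves for the free scale parameters of the AI and LSI formulas so that,
#' under constant reference inputs, each index crosses its clinical target at
#' a requested time: the AI scale `K` is solved given the exponents
#' (`a`, `b`, `c`), and the LSI term scales (`b0`, `b2`) are solved jointly
#' (at a fixed force-term share) given the shape constants
#' (`b1`, `b3`, `b4`, `b5`). This pins the synthetic cohort's ground truth to
#' the clinical targets (AI >= 400 and LSI >= 4) without pretending to know
#' the proprietary coefficients.
#'
#' @param target_ai AI target value (default 400).
#' @param t_ai_s time (s) at which the AI oracle should cross `target_ai`
#'   under the reference inputs.
#' @param target_lsi LSI target value (default 4).
#' @param t_lsi_s time (s) at which the LSI oracle should cross `target_lsi`.
#' @param cf_ref reference contact force, g.
#' @param power_ref reference power, W.
#' @param current_ref reference RF current, mA.
#' @param a,b,c AI exponents (see [ai_constants()]).
#' @param b1,b3,b4,b5 LSI shape constants (see [lsi_constants()]).
#' @param b0_frac share of the calibrated LSI amplitude assigned to the
#'   force term (the rest goes to the current term).
#' @param max_amplitude feasibility cap on `b0 + b2`; a requested target that
#'   would need a larger saturation amplitude is rejected.
#' @return A list with elements `ai` (class `ai_constants`) and `lsi`
#'   (class `lsi_constants`).
#' @examples
#' cs <- calibrate_constants(t_ai_s = 7, t_lsi_s = 20)
#' cs$ai$K
#' @export
calibrate_constants <- function(target_ai = 400, t_ai_s = 7,
                                target_lsi = 4, t_lsi_s = 20,
                                cf_ref = 15, power_ref = 40, current_ref = 500,
                                a = 0.6, b = 1.4, c = 0.35,
                                b1 = 8, b3 = 2.5e5, b4 = 0.85, b5 = 30,
                                b0_frac = 0.35, max_amplitude = 12) {
  stopifnot(t_ai_s > 0, t_lsi_s > 0, cf_ref > 0, power_ref > 0, current_ref > 0)
  if (target_ai <= 0 || target_lsi <= 0)
    stop("calibrate_constants: targets must be > 0", call. = FALSE)
  if (b0_frac < 0 || b0_frac > 1)
    stop("calibrate_constants: b0_frac must lie in [0, 1]", call. = FALSE)

  # AI under constant CF, P: AI(t) = K * (CF^a P^b t)^c  =>  K = target / (...)^c
  K <- target_ai / (cf_ref^a * power_ref^b * t_ai_s)^c

  # LSI under constant F, I: amplitude * saturation_mix(F, I) * time_factor(t)
  sat_f <- 1 - exp(-cf_ref / b1)
  sat_i <- 1 - exp(-current_ref^2 / b3)
  tf <- (1 - b4) + b4 * (1 - exp(-t_lsi_s / b5)) / (1 - exp(-60 / b5))
  mix <- b0_frac * sat_f + (1 - b0_frac) * sat_i
  amplitude <- target_lsi / (mix * tf)
  if (!is.finite(amplitude) || amplitude > max_amplitude) {
    stop(sprintf(paste0("calibrate_constants: infeasible LSI target: requires ",
                        "saturation amplitude b0 + b2 = %.3f > cap %.3f"),
                 amplitude, max_amplitude), call. = FALSE)
  }
  list(
    ai  = ai_constants(K = K, a = a, b = b, c = c),
    lsi = lsi_constants(b0 = b0_frac * amplitude, b1 = b1,
                        b2 = (1 - b0_frac) * amplitude, b3 = b3,
                        b4 = b4, b5 = b5)
  )
}

#' Default stand-in metric constants of the synthetic study
#'
#' The calibration used throughout the analysis scripts: the AI oracle
#' crosses 400 at 7.3 s and the LSI oracle crosses 4 at 19.9 s under the
#' cohort's typical operating point (CF 18 g, 40 W, 540 mA), so the
#' synthetic cohort reproduces the qualitative stopping-rule ordering
#' (AI target before LI plateau before LSI target) by construction.
#'
#' @return A list with `ai` and `lsi` constants.
#' @export
default_metric_constants <- function() {
  calibrate_constants(t_ai_s = 7.3, t_lsi_s = 19.9,
                      cf_ref = 18, power_ref = 40, current_ref = 540)
}

#' Read metric constants from a plain-text config file
#'
#' The config is a flat `key = value` file with keys `ai.K`, `ai.a`, `ai.b`,
#' `ai.c` and `lsi.b0` ... `lsi.b5`. Lines starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @return A list with elements `ai` and `lsi` as in [calibrate_constants()].
#' @export
read_metric_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("read_metric_config: malformed line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("read_metric_config: missing key ", k, call. = FALSE)
    vals[i]
  }
  list(
    ai = ai_constants(get("ai.K"), get("ai.a"), get("ai.b"), get("ai.c")),
    lsi = lsi_constants(get("lsi.b0"), get("lsi.b1"), get("lsi.b2"),
                        get("lsi.b3"), get("lsi.b4"), get("lsi.b5"))
  )
}

#' Write metric constants to a plain-text config file
#'
#' @param constants list with `ai` and `lsi` elements as returned by
#'   [calibrate_constants()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_metric_config <- function(constants, path) {
  stopifnot(inherits(constants$ai, "ai_constants"),
            inherits(constants$lsi, "lsi_constants"))
  ai <- constants$ai; lsi <- constants$lsi
  lines <- c(
    "# stand-in lesion-index constants (not the proprietary values)",
    sprintf("ai.%s = %.17g", names(ai), unlist(ai)),
    sprintf("lsi.%s = %.17g", names(lsi), unlist(lsi))
  )
  writeLines(lines, path)
  invisible(path)
}
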