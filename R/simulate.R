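# Synthetic ablation cohort: per-lesion traces (CF, power, LI, tip position)
# with known ground truth, ring-layout procedures, and controlled
# missingness. Replaces the clinical mapping-system exports, which are not
# publicly available, with a generator whose every quantity has a closed
# form the pipeline can be tested against.

#' Parameters of one synthetic ablation trace
#'
#' The local-impedance model is an exponential drop with a linear rebound,
#' \deqn{LI(t) = LI_0 - drop \cdot (1 - e^{-t/\tau}) + rebound \cdot t + \epsilon(t),}
#' the simplest shape with a guaranteed, tunable interior minimum: for
#' `rebound_ohm_per_s > 0` the noiseless curve has its unique minimum at
#' \eqn{t^* = \tau \log(drop / (\tau \cdot rebound))}, the analytic oracle
#' for plateau-detection tests. Contact force is the mean plus an AR(1)
#' wobble (so windowed means genuinely differ from instantaneous values),
#' power is a constant setting, and the catheter tip wobbles around the
#' lesion centre.
#'
#' @param duration_s trace duration, s (> 0).
#' @param cf_mean_g mean contact force, g (>= 0).
#' @param cf_sd_g SD of the within-lesion CF wobble, g.
#' @param power_w power setting, W.
#' @param li0_ohm starting local impedance, ohm.
#' @param drop_ohm asymptotic LI drop, ohm (0 < drop < li0).
#' @param tau_drop_s exponential decay constant of the drop, s (> 0).
#' @param rebound_ohm_per_s post-plateau drift slope, ohm/s (>= 0).
#' @param noise_sd_ohm SD of additive LI noise, ohm.
#' @param sample_hz nominal raw sampling rate, Hz; actual sampling is
#'   irregular (uniform jitter on the inter-sample gaps) so resampling is
#'   genuinely exercised.
#' @param seed integer seed; generation is bit-reproducible from it.
#' @return An object of class `trace_params`.
#' @export
trace_params <- function(duration_s, cf_mean_g, cf_sd_g = 2, power_w = 40,
                         li0_ohm = 150, drop_ohm = 25, tau_drop_s = 5,
                         rebound_ohm_per_s = 0.4, noise_sd_ohm = 0.5,
                         sample_hz = 50, seed = 1L) {
  fail <- function(msg) stop("trace_params: ", msg, call. = FALSE)
  if (!is.numeric(duration_s) || duration_s <= 0) fail("duration_s must be > 0")
  if (cf_mean_g < 0) fail("cf_mean_g must be >= 0")
  if (cf_sd_g < 0) fail("cf_sd_g must be >= 0")
  if (power_w < 0) fail("power_w must be >= 0")
  if (!(li0_ohm > drop_ohm && drop_ohm > 0)) fail("need li0_ohm > drop_ohm > 0")
  if (tau_drop_s <= 0) fail("tau_drop_s must be > 0")
  if (rebound_ohm_per_s < 0) fail("rebound_ohm_per_s must be >= 0")
  if (noise_sd_ohm < 0) fail("noise_sd_ohm must be >= 0")
  if (sample_hz <= 0) fail("sample_hz must be > 0")
  structure(list(duration_s = duration_s, cf_mean_g = cf_mean_g,
                 cf_sd_g = cf_sd_g, power_w = power_w, li0_ohm = li0_ohm,
                 drop_ohm = drop_ohm, tau_drop_s = tau_drop_s,
                 rebound_ohm_per_s = rebound_ohm_per_s,
                 noise_sd_ohm = noise_sd_ohm, sample_hz = sample_hz,
                 seed = as.integer(seed)),
            class = "trace_params")
}

#' Analytic LI minimum of a noiseless trace
#'
#' Closed-form location of the interior minimum of the noiseless LI curve,
#' \eqn{t^* = \tau \log(drop/(\tau \cdot rebound))}, clamped to the trace:
#' with no rebound (or a minimum beyond the trace end) the infimum sits at
#' the final sample.
#'
#' @param params a [trace_params()] object.
#' @return Time of the noiseless minimum, s.
#' @export
noiseless_li_minimum <- function(params) {
  stopifnot(inherits(params, "trace_params"))
  if (params$rebound_ohm_per_s <= 0) return(params$duration_s)
  tstar <- params$tau_drop_s *
    log(params$drop_ohm / (params$tau_drop_s * params$rebound_ohm_per_s))
  min(max(tstar, 0), params$duration_s)
}

noiseless_li <- function(t, params) {
  params$li0_ohm - params$drop_ohm * (1 - exp(-t / params$tau_drop_s)) +
    params$rebound_ohm_per_s * t
}

#' Simulate one ablation trace
#'
#' Generates an irregularly sampled raw trace (time, CF, power, LI, tip
#' coordinates) from [trace_params()]. See that help page for the signal
#' model. With `noise_sd_ohm = 0` and `rebound_ohm_per_s = 0` the LI series
#' is strictly decreasing; with a positive rebound the noiseless curve has
#' exactly one interior local minimum.
#'
#' @param params a [trace_params()] object.
#' @param centre_mm lesion centre, length-3 numeric (mm).
#' @param tip_jitter_mm SD of the per-sample tip wobble, mm.
#' @param procedure_id,lesion_id identifiers carried through the pipeline.
#' @return An `ablation_trace`: a data frame with columns `procedure_id`,
#'   `lesion_id`, `time_s`, `cf_g`, `power_w`, `li_ohm`, `x_mm`, `y_mm`,
#'   `z_mm`, with the generating parameters attached as attribute `params`.
#' @export
simulate_trace <- function(params, centre_mm = c(0, 0, 0), tip_jitter_mm = 0.3,
                           procedure_id = "P1", lesion_id = "L1") {
  stopifnot(inherits(params, "trace_params"))
  if (length(centre_mm) != 3L) stop("simulate_trace: centre_mm must have length 3",
                                    call. = FALSE)
  p <- params
  withr_seed <- p$seed
  old <- get_global_rng_state()
  set.seed(withr_seed)
  on.exit(restore_rng_state(old), add = TRUE)

  # irregular sampling: inter-sample gaps jittered uniformly in [0.5, 1.5]/fs
  n_nominal <- max(2L, ceiling(p$duration_s * p$sample_hz))
  gaps <- stats::runif(n_nominal * 2L, 0.5, 1.5) / p$sample_hz
  t <- cumsum(c(0, gaps))
  t <- t[t <= p$duration_s]
  if (length(t) < 2L) t <- c(0, p$duration_s)
  n <- length(t)

  # CF: mean + AR(1)-smoothed wobble, floored at 0
  phi <- 0.95
  innov <- stats::rnorm(n, 0, p$cf_sd_g * sqrt(1 - phi^2))
  wob <- as.numeric(stats::filter(innov, phi, method = "recursive"))
  cf <- pmax(0, p$cf_mean_g + wob)

  li <- noiseless_li(t, p) + stats::rnorm(n, 0, p$noise_sd_ohm)
  li <- pmax(li, 1)  # impedance stays physical under extreme noise draws

  tip <- matrix(stats::rnorm(3L * n, 0, tip_jitter_mm), ncol = 3L)
  tip <- sweep(tip, 2L, centre_mm, "+")

  out <- data.frame(
    procedure_id = procedure_id, lesion_id = lesion_id,
    time_s = t, cf_g = cf, power_w = p$power_w, li_ohm = li,
    x_mm = tip[, 1L], y_mm = tip[, 2L], z_mm = tip[, 3L],
    stringsAsFactors = FALSE
  )
  attr(out, "params") <- p
  class(out) <- c("ablation_trace", "data.frame")
  out
}

get_global_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Layout of one synthetic procedure
#'
#' Lesion centres are placed at equal angles on a ring (the geometry of an
#' encircling pulmonary-vein lesion set) plus Gaussian jitter, so
#' neighbouring-lesion distances concentrate near the chord
#' \eqn{2 R \sin(\pi/n)}. Defaults (R = 17.5 mm, n = 30) put the median
#' interlesion distance near 3.7 mm.
#'
#' @param n_lesions number of lesions (>= 1).
#' @param ring_radius_mm ring radius, mm (> 0).
#' @param spacing_jitter_mm SD of the placement jitter, mm.
#' @param tip_jitter_mm SD of the per-sample catheter-tip wobble, mm.
#' @param seed integer seed.
#' @return An object of class `procedure_layout`.
#' @export
procedure_layout <- function(n_lesions = 30, ring_radius_mm = 18.5,
                             spacing_jitter_mm = 0.4, tip_jitter_mm = 0.3,
                             seed = 1L) {
  if (n_lesions < 1) stop("procedure_layout: n_lesions must be >= 1", call. = FALSE)
  if (ring_radius_mm <= 0) stop("procedure_layout: ring_radius_mm must be > 0",
                                call. = FALSE)
  structure(list(n_lesions = as.integer(n_lesions),
                 ring_radius_mm = ring_radius_mm,
                 spacing_jitter_mm = spacing_jitter_mm,
                 tip_jitter_mm = tip_jitter_mm, seed = as.integer(seed)),
            class = "procedure_layout")
}

#' Default sampler of per-lesion trace parameters
#'
#' Draws [trace_params()] whose marginals emulate the clinical summaries the
#' pipeline is aimed at: contact force lognormal around 18 g (IQR roughly
#' 12--25 g), starting LI normal around 147 ohm, asymptotic LI drop lognormal
#' around 28 ohm (so the realised drop at the plateau sits near 20 ohm),
#' power fixed at the 40 W setting, and LI dynamics whose analytic minimum
#' falls around 12 s with a spread of roughly 8--17 s.
#'
#' @param duration_range_s trace duration range, s (drawn uniformly).
#' @param power_w power setting, W.
#' @param noise_sd_ohm LI noise SD, ohm.
#' @param sample_hz nominal raw sampling rate, Hz.
#' @return A function `(seed) -> trace_params`.
#' @export
default_trace_sampler <- function(duration_range_s = c(24, 30), power_w = 40,
                                  noise_sd_ohm = 0.5, sample_hz = 50) {
  force(duration_range_s); force(power_w); force(noise_sd_ohm); force(sample_hz)
  function(seed) {
    old <- get_global_rng_state()
    set.seed(seed)
    on.exit(restore_rng_state(old), add = TRUE)
    cf_mean <- stats::rlnorm(1, log(18), 0.42)
    drop <- stats::rlnorm(1, log(36), 0.3)
    li0 <- stats::rnorm(1, 147, 9)
    li0 <- max(li0, drop + 40)
    tau <- stats::runif(1, 4, 6.5)
    # rebound set so the analytic minimum lands near a target drawn around
    # 12 s (lognormal, IQR ~ 8.5-16 s), then clipped to keep rebound modest
    t_star <- stats::rlnorm(1, log(12), 0.45)
    t_star <- min(max(t_star, 5), 22)
    rebound <- drop / (tau * exp(t_star / tau))
    trace_params(
      duration_s = stats::runif(1, duration_range_s[1L], duration_range_s[2L]),
      cf_mean_g = cf_mean, cf_sd_g = 0.12 * cf_mean, power_w = power_w,
      li0_ohm = li0, drop_ohm = drop, tau_drop_s = tau,
      rebound_ohm_per_s = rebound, noise_sd_ohm = noise_sd_ohm,
      sample_hz = sample_hz, seed = seed
    )
  }
}

#' Simulate a full procedure (one lesion set)
#'
#' Places `layout$n_lesions` centres on the jittered ring and simulates one
#' trace per centre with parameters drawn from `trace_params_sampler`. All
#' per-lesion seeds derive deterministically from `seed`.
#'
#' @param layout a [procedure_layout()] object.
#' @param trace_params_sampler a function `(seed) -> trace_params`, e.g.
#'   [default_trace_sampler()].
#' @param seed integer seed for the whole procedure.
#' @param procedure_id identifier stamped on every trace.
#' @return A list of `ablation_trace` data frames with distinct lesion IDs;
#'   lesion centres attached as attribute `centres` (n x 3 matrix).
#' @export
simulate_procedure <- function(layout, trace_params_sampler = default_trace_sampler(),
                               seed = 1L, procedure_id = "P1") {
  stopifnot(inherits(layout, "procedure_layout"))
  old <- get_global_rng_state()
  set.seed(seed)
  on.exit(restore_rng_state(old), add = TRUE)
  n <- layout$n_lesions
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  centres <- cbind(layout$ring_radius_mm * cos(theta),
                   layout$ring_radius_mm * sin(theta),
                   rep(0, n))
  centres <- centres + matrix(stats::rnorm(3L * n, 0, layout$spacing_jitter_mm),
                              ncol = 3L)
  lesion_seeds <- (as.integer(seed) %% 100000L) * 10000L + seq_len(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    p <- trace_params_sampler(lesion_seeds[i])
    traces[[i]] <- simulate_trace(p, centre_mm = centres[i, ],
                                  tip_jitter_mm = layout$tip_jitter_mm,
                                  procedure_id = procedure_id,
                                  lesion_id = sprintf("%s-L%03d", procedure_id, i))
  }
  attr(traces, "centres") <- centres
  traces
}

#' Simulate a multi-procedure cohort
#'
#' @param n_procedures number of procedures.
#' @param layout a [procedure_layout()]; reused for every procedure.
#' @param trace_params_sampler per-lesion parameter sampler.
#' @param seed master seed; per-procedure seeds derive from it.
#' @return A flat list of `ablation_trace` objects across procedures.
#' @export
simulate_cohort <- function(n_procedures, layout = procedure_layout(),
                            trace_params_sampler = default_trace_sampler(),
                            seed = 1L) {
  out <- list()
  for (k in seq_len(n_procedures)) {
    pid <- sprintf("P%03d", k)
    tr <- simulate_procedure(layout, trace_params_sampler,
                             seed = (as.integer(seed) + 7L * k) %% .Machine$integer.max,
                             procedure_id = pid)
    out <- c(out, tr)
  }
  out
}

#' Missingness specification
#'
#' @param mechanism `"MCAR"` (uniform deletion) or `"MAR"` (deletion
#'   probability increasing in a fully observed driver covariate).
#' @param rate overall expected missing fraction in `[0, 1)`.
#' @param driver_column covariate driving MAR deletion (required iff MAR).
#' @param seed integer seed.
#' @param slope logistic slope on the standardised driver (MAR strength).
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(mechanism = c("MCAR", "MAR"), rate,
                             driver_column = NULL, seed = 1L, slope = 2) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1)
    stop("missingness_spec: rate must lie in [0, 1)", call. = FALSE)
  if (mechanism == "MAR" && is.null(driver_column))
    stop("missingness_spec: MAR requires driver_column", call. = FALSE)
  if (mechanism == "MCAR" && !is.null(driver_column))
    driver_column <- NULL
  structure(list(mechanism = mechanism, rate = rate,
                 driver_column = driver_column, seed = as.integer(seed),
                 slope = slope),
            class = "missingness_spec")
}

#' Inject missingness into a lesion-summary column
#'
#' MCAR deletes entries uniformly at the requested rate; MAR deletes with a
#' logistic probability increasing in the (standardised) driver column, its
#' intercept solved so the expected overall rate matches `spec$rate`. The
#' returned table carries the pre-deletion truth as attribute `mask` (a list
#' with the logical missing indicator and the original values) so recovery
#' tests can score imputations.
#'
#' @param table a data frame (lesion summaries).
#' @param spec a [missingness_spec()] object.
#' @param target_column column to delete from (default `duration_lsi_s`).
#' @return The table with `NA`s injected; attributes `mask` and `spec`.
#' @export
inject_missingness <- function(table, spec, target_column = "duration_lsi_s") {
  stopifnot(inherits(spec, "missingness_spec"))
  if (!target_column %in% names(table))
    stop("inject_missingness: target column not found: ", target_column,
         call. = FALSE)
  n <- nrow(table)
  old <- get_global_rng_state()
  set.seed(spec$seed)
  on.exit(restore_rng_state(old), add = TRUE)
  if (spec$rate == 0) {
    miss <- rep(FALSE, n)
  } else if (spec$mechanism == "MCAR") {
    miss <- stats::runif(n) < spec$rate
  } else {
    z <- table[[spec$driver_column]]
    if (is.null(z)) stop("inject_missingness: driver column not found: ",
                         spec$driver_column, call. = FALSE)
    z <- as.numeric(scale(z))
    z[!is.finite(z)] <- 0
    intercept <- stats::uniroot(
      function(a) mean(stats::plogis(a + spec$slope * z)) - spec$rate,
      interval = c(-50, 50)
    )$root
    miss <- stats::runif(n) < stats::plogis(intercept + spec$slope * z)
  }
  truth <- table[[target_column]]
  table[[target_column]][miss] <- NA_real_
  attr(table, "mask") <- list(missing = miss, truth = truth,
                              column = target_column)
  attr(table, "spec") <- spec
  table
}
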