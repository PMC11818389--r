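# Reference formula implementations: cumulative Simpson integration,
# Ohm's-law current, windowed means, and the AI/LSI oracles.

test_that("cumulative Simpson matches closed-form antiderivatives", {
  t5 <- seq(0, 5, by = 0.01)
  expect_equal(force_time_integral(rep(10, length(t5)), t5),
               10 * t5, tolerance = 1e-12)

  t2 <- seq(0, 2, by = 0.05)
  expect_equal(force_time_integral(t2, t2), t2^2 / 2, tolerance = 1e-12)

  t1 <- seq(0, 1, length.out = 998) # ~997 Hz
  fti <- force_time_integral(exp(t1), t1)
  expect_lt(max(abs(fti[-1] - (exp(t1[-1]) - 1)) / (exp(t1[-1]) - 1)), 1e-8)
})

test_that("cumulative Simpson is exact on cubics at every grid point", {
  tt <- seq(0, 2, by = 0.1)
  f <- 3 * tt^3 - 2 * tt^2 + tt - 4
  truth <- 3 * tt^4 / 4 - 2 * tt^3 / 3 + tt^2 / 2 - 4 * tt
  expect_equal(force_time_integral(f, tt), truth, tolerance = 1e-12)
})

test_that("integration rejects non-uniform grids and single samples", {
  expect_error(force_time_integral(c(1, 2, 3), c(0, 0.1, 0.3)), "uniform")
  expect_error(force_time_integral(1, 0), "2 samples")
  # two samples fall back to the trapezoid
  expect_equal(force_time_integral(c(2, 4), c(0, 1)), c(0, 3))
})

test_that("integral is non-decreasing for smooth non-negative integrands", {
  set.seed(1)
  tt <- seq(0, 10, by = 0.01)
  cf <- pmax(0, 15 + as.numeric(stats::filter(rnorm(length(tt)), 0.95,
                                              method = "recursive")))
  expect_true(all(diff(force_time_integral(cf, tt)) >= -1e-9))
})

test_that("RF current follows Ohm's law and round-trips to power", {
  expect_equal(rf_current(40, 160), 500)
  expect_equal(rf_current(0, 150), 0)
  i <- rf_current(40, 144.6)
  expect_lt(abs((i / 1000)^2 * 144.6 - 40) / 40, 1e-10)
  expect_error(rf_current(40, 0), "impedance")
  expect_error(rf_current(-1, 150), "power")
})

test_that("trailing window mean truncates at the trace start", {
  tt <- seq(0, 10, by = 0.1)
  expect_equal(sliding_window_mean(rep(7, length(tt)), tt), rep(7, length(tt)))
  # step at t = 0: any truncated window is fully post-step
  step <- rep(10, length(tt))
  expect_equal(sliding_window_mean(step, tt, 6)[tt == 3], 10)
  # ramp vs direct per-index averaging
  x <- tt * 2
  w <- round(6 / 0.1)
  brute <- vapply(seq_along(x), function(i) mean(x[max(1, i - w + 1):i]),
                  numeric(1))
  expect_equal(sliding_window_mean(x, tt, 6), brute, tolerance = 1e-12)
  expect_error(sliding_window_mean(x, tt, 0), "window_s")
})

test_that("AI reduces to its closed form under constant inputs", {
  tt <- seq(0, 10, by = 1 / 997)
  cs <- ai_constants(K = 1, a = 0, b = 0, c = 1)
  expect_equal(ablation_index(rep(3, length(tt)), rep(50, length(tt)), tt, cs),
               tt, tolerance = 1e-9)

  cs2 <- ai_constants(K = 2, a = 0.6, b = 1.4, c = 0.35)
  ai <- ablation_index(rep(15, length(tt)), rep(40, length(tt)), tt, cs2)
  truth <- 2 * (15^0.6 * 40^1.4 * tt)^0.35
  expect_lt(max(abs(ai[-1] - truth[-1]) / truth[-1]), 1e-6)

  # zero CF with a positive force exponent kills the index
  expect_equal(ablation_index(rep(0, length(tt)), rep(40, length(tt)), tt, cs2),
               rep(0, length(tt)))
  expect_error(ablation_index(rep(-1, length(tt)), rep(40, length(tt)), tt, cs2),
               ">= 0")
})

test_that("AI is monotone, starts at zero, and is scale-equivariant in K", {
  set.seed(2)
  tt <- seq(0, 8, by = 0.005)
  cf <- pmax(0, 18 + as.numeric(stats::filter(rnorm(length(tt), 0, 0.6), 0.95,
                                              method = "recursive")))
  cs <- ai_constants(K = 5, a = 0.6, b = 1.4, c = 0.35)
  ai <- ablation_index(cf, rep(40, length(tt)), tt, cs)
  expect_equal(ai[1], 0)
  expect_true(all(diff(ai) >= -1e-9))
  cs3 <- ai_constants(K = 3 * cs$K, a = cs$a, b = cs$b, c = cs$c)
  expect_equal(ablation_index(cf, rep(40, length(tt)), tt, cs3), 3 * ai,
               tolerance = 1e-12)
})

test_that("LSI time factor cancels at 60 s and saturates at b0 + b2", {
  cc <- lsi_constants(b0 = 2, b1 = 10, b2 = 3, b3 = 2.5e5, b4 = 0.6, b5 = 12)
  f <- 15; i <- 500
  expect_equal(lsi_pointwise(f, i, 60, cc),
               cc$b0 * (1 - exp(-f / cc$b1)) + cc$b2 * (1 - exp(-i^2 / cc$b3)),
               tolerance = 1e-12)
  expect_equal(lsi_pointwise(1e9, 1e9, 60, cc), cc$b0 + cc$b2, tolerance = 1e-9)
})

test_that("LSI series matches a literal transcription of the formula", {
  cc <- lsi_constants(b0 = 2.1, b1 = 9, b2 = 2.9, b3 = 2.2e5, b4 = 0.7, b5 = 15)
  # independent single-expression evaluation
  literal <- function(f, i, tau) {
    (cc$b0 * (1 - exp(-f / cc$b1)) + cc$b2 * (1 - exp(-i^2 / cc$b3))) *
      ((1 - cc$b4) + cc$b4 * (1 - exp(-tau / cc$b5)) / (1 - exp(-60 / cc$b5)))
  }
  expect_equal(lsi_pointwise(15, 500, 10, cc), literal(15, 500, 10),
               tolerance = 1e-12)

  # full series path: constant inputs so the windowed means are the inputs
  tt <- seq(0, 30, by = 0.01)
  lsi <- lesion_size_index(rep(15, length(tt)), rep(500, length(tt)), tt, cc)
  expect_equal(lsi, literal(15, 500, tt), tolerance = 1e-12)
  expect_true(all(diff(lsi) >= 0))
  expect_true(all(lsi >= 0 & lsi <= cc$b0 + cc$b2))
})

test_that("constant calibration hits the requested crossing times", {
  tt <- seq(0, 30, by = 1 / 997)
  cs <- calibrate_constants(target_ai = 400, t_ai_s = 7, target_lsi = 4,
                            t_lsi_s = 20, cf_ref = 15, power_ref = 40,
                            current_ref = 500)
  ai <- ablation_index(rep(15, length(tt)), rep(40, length(tt)), tt, cs$ai)
  expect_lt(abs(time_to_target(tt, ai, 400) - 7), 2 / 997)
  lsi <- lesion_size_index(rep(15, length(tt)), rep(500, length(tt)), tt, cs$lsi)
  expect_lt(abs(time_to_target(tt, lsi, 4) - 20), 2 / 997)
})

test_that("infeasible LSI targets are rejected with a diagnostic", {
  expect_error(calibrate_constants(target_lsi = 50, t_lsi_s = 20),
               "infeasible")
})

test_that("constants validate their invariants", {
  expect_error(ai_constants(K = -1, a = 0.6, b = 1.4, c = 0.35), "K")
  expect_error(ai_constants(K = 1, a = 0.6, b = 1.4, c = 0), "c")
  expect_error(lsi_constants(2, -1, 3, 2.5e5, 0.5, 12), "b1")
  expect_error(lsi_constants(2, 10, 3, 2.5e5, 1.5, 12), "b4")
})

test_that("metric config round-trips through the plain-text format", {
  cs <- calibrate_constants()
  path <- withr::local_tempfile(fileext = ".cfg")
  write_metric_config(cs, path)
  back <- read_metric_config(path)
  expect_equal(unclass(back$ai), unclass(cs$ai))
  expect_equal(unclass(back$lsi), unclass(cs$lsi))
})
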