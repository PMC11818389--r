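# Resampling, LI filtering, plateau detection, targets, geometry, and
# per-lesion summaries.

test_that("resampling is the identity on an already-uniform grid", {
  tt <- seq(0, 5, by = 1 / 997)
  tr <- make_uniform_trace(tt, li = 150 - 2 * tt)
  out <- resample_trace(tr, 997)
  expect_equal(out$time_s, tt, tolerance = 1e-9)
  expect_equal(out$li_ohm, tr$li_ohm, tolerance = 1e-9)
  # idempotence of the resampling stage
  out2 <- resample_trace(out, 997)
  expect_equal(out2$li_ohm, out$li_ohm, tolerance = 1e-9)
})

test_that("piecewise-linear channels are reproduced exactly on the grid", {
  set.seed(6)
  t_raw <- sort(c(0, 12, stats::runif(200, 0, 12)))
  tr <- make_uniform_trace(t_raw, li = 150 - 2 * t_raw, cf = 3 + 0.5 * t_raw)
  out <- resample_trace(tr, 997)
  expect_equal(out$li_ohm, 150 - 2 * out$time_s, tolerance = 1e-9)
  expect_equal(out$cf_g, 3 + 0.5 * out$time_s, tolerance = 1e-9)
})

test_that("interpolation error on a sine channel obeys the curvature bound", {
  set.seed(7)
  gaps <- stats::runif(12000, 0.5, 1.5) / 997
  t_raw <- cumsum(c(0, gaps))
  amp <- 2
  tr <- make_uniform_trace(t_raw, li = 150 + amp * sin(2 * pi * 5 * t_raw))
  out <- resample_trace(tr, 997)
  err <- max(abs(out$li_ohm - (150 + amp * sin(2 * pi * 5 * out$time_s))))
  bound <- max(gaps)^2 * (2 * pi * 5)^2 * amp / 8
  expect_lt(err, bound * 1.0001)
})

test_that("resampling rejects degenerate inputs", {
  tr <- make_uniform_trace(c(0, 1, 1), li = c(150, 149, 148))
  expect_error(resample_trace(tr), "strictly increasing")
  tr1 <- make_uniform_trace(0, li = 150)
  expect_error(resample_trace(tr1), "2 raw samples")
})

test_that("LI filter passes constants, trims the left edge, stays in range", {
  tt <- seq(0, 10, by = 1 / 997)
  tr <- make_uniform_trace(tt, li = rep(150, length(tt)))
  attr(tr, "fs_hz") <- 997
  ft <- filter_li(tr)
  expect_equal(ft$li_filtered_ohm, rep(150, nrow(ft)))
  expect_equal(attr(ft, "trim_offset_s"), 0.75, tolerance = 2 / 997)

  set.seed(8)
  noisy <- make_uniform_trace(tt, li = 150 + stats::rnorm(length(tt)))
  attr(noisy, "fs_hz") <- 997
  fn <- filter_li(noisy)
  expect_true(all(fn$li_filtered_ohm >= min(noisy$li_ohm)))
  expect_true(all(fn$li_filtered_ohm <= max(noisy$li_ohm)))
  expect_error(filter_li(make_uniform_trace(seq(0, 1, by = 0.01),
                                            li = rep(1, 101))), "window")
})

test_that("moving mean is exact on affine signals over full support", {
  tt <- seq(0, 10, by = 0.01)
  tr <- make_uniform_trace(tt, li = 140 + 1.5 * tt)
  attr(tr, "fs_hz") <- 100
  ft <- filter_li(tr, window_s = 1.5)
  n <- nrow(ft)
  full <- seq_len(n - 76)  # right edge shrinks over the last half-window
  expect_equal(ft$li_filtered_ohm[full], 140 + 1.5 * ft$time_s[full],
               tolerance = 1e-9)
})

test_that("white-noise SD shrinks by the square root of the window size", {
  set.seed(9)
  tt <- seq(0, 300, by = 0.01)
  tr <- make_uniform_trace(tt, li = 150 + stats::rnorm(length(tt)))
  attr(tr, "fs_hz") <- 100
  ft <- filter_li(tr, window_s = 1.5)
  w <- 151
  interior <- 100:(nrow(ft) - 100)
  ratio <- stats::sd(ft$li_filtered_ohm[interior] - 150) / (1 / sqrt(w))
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("plateau detection finds a constructed vertex and flags no rebound", {
  tt <- seq(0, 30, by = 1 / 997)
  # symmetric V so the centered moving mean preserves the vertex location
  v <- 150 - 1.5 * pmin(tt, 12) + 1.5 * pmax(0, tt - 12)
  tr <- make_uniform_trace(tt, li = v)
  attr(tr, "fs_hz") <- 997
  ft <- filter_li(tr)
  pl <- detect_plateau(ft)
  expect_lt(abs(pl$t_plateau_s - 12), 0.05)
  expect_equal(pl$li_drop_ohm, pl$li_start_ohm - pl$li_at_plateau_ohm)
  expect_false(pl$no_rebound)

  dec <- make_uniform_trace(tt, li = 150 - tt)
  attr(dec, "fs_hz") <- 997
  pl2 <- detect_plateau(filter_li(dec))
  expect_true(pl2$no_rebound)
  expect_equal(pl2$t_plateau_s, 30, tolerance = 0.01)
})

test_that("local-minimum detector honours its prominence threshold", {
  tt <- seq(0, 30, by = 0.01)
  # shallow dip at 8 s (depth ~0.2) and deep dip at 16 s
  li <- 150 - 1.2 * pmin(tt, 16) + 0.9 * pmax(0, tt - 16) +
    0.2 * sin(2 * pi * tt / 16)
  tr <- make_uniform_trace(tt, li = li)
  attr(tr, "fs_hz") <- 100
  pl <- detect_plateau(filter_li(tr), method = "local", prominence_ohm = 1)
  expect_lt(abs(pl$t_plateau_s - detect_plateau(filter_li(tr))$t_plateau_s),
            0.2)
})

test_that("time to target crosses on the grid and censors correctly", {
  tt <- seq(0, 10, by = 1 / 997)
  expect_lt(abs(time_to_target(tt, (400 / 7) * tt, 400) - 7), 2 / 997)
  expect_true(is.na(time_to_target(tt, rep(380, length(tt)), 400)))
  expect_error(time_to_target(tt, tt, -1), "target")
})

test_that("mean tip position averages coordinates", {
  tr <- make_uniform_trace(c(0, 1), li = c(150, 149))
  tr$x_mm <- c(0, 2); tr$y_mm <- c(0, 0); tr$z_mm <- c(0, 0)
  expect_equal(unname(mean_tip_position(tr)), c(1, 0, 0))

  set.seed(10)
  n <- 997
  tr2 <- make_uniform_trace(seq(0, 1, length.out = n), li = rep(150, n))
  tr2$x_mm <- stats::rnorm(n, 3, 0.5)
  tr2$y_mm <- stats::rnorm(n, -1, 0.5)
  tr2$z_mm <- stats::rnorm(n, 7, 0.5)
  mp <- mean_tip_position(tr2)
  expect_true(all(abs(mp - c(3, -1, 7)) < 4 * 0.5 / sqrt(n)))
})

test_that("interlesion distances match hand geometry and the brute-force scan", {
  pos <- data.frame(procedure_id = "P1", lesion_id = c("a", "b"),
                    x_mm = c(0, 3), y_mm = c(0, 4), z_mm = c(0, 0))
  expect_equal(interlesion_distance(pos), c(5, 5))

  col <- data.frame(procedure_id = "P1", lesion_id = c("a", "b", "c"),
                    x_mm = c(0, 2, 7), y_mm = 0, z_mm = 0)
  expect_equal(interlesion_distance(col), c(2, 2, 5))

  set.seed(11)
  pos50 <- data.frame(procedure_id = rep(c("P1", "P2"), c(30, 20)),
                      lesion_id = as.character(1:50),
                      x_mm = stats::rnorm(50, 0, 10),
                      y_mm = stats::rnorm(50, 0, 10),
                      z_mm = stats::rnorm(50, 0, 10))
  expect_equal(interlesion_distance(pos50), ild_bruteforce(pos50))

  # singleton procedures stay NA
  single <- data.frame(procedure_id = "P9", lesion_id = "only",
                       x_mm = 1, y_mm = 2, z_mm = 3)
  expect_true(is.na(interlesion_distance(single)))
})

test_that("lesion summaries read constructed values off the series", {
  tt <- seq(0, 30, by = 1 / 997)
  li <- 150 - 1.5 * pmin(tt, 12) + 0.8 * pmax(0, tt - 12)
  tr <- make_uniform_trace(tt, li = li, cf = rep(18, length(tt)))
  attr(tr, "fs_hz") <- 997
  ft <- filter_li(tr)
  pl <- detect_plateau(ft)
  tau <- ft$time_s - ft$time_s[1]
  # constructed AI crossing 476.46 exactly at the plateau
  ai <- 476.46 * tau / (pl$t_plateau_s - ft$time_s[1])
  lsi <- 4 * tau / 20
  ls <- summarize_lesion(ft, pl, ai, lsi)
  expect_equal(ls$cf_mean_g, 18)
  expect_equal(ls$cf_start_g, 18)
  expect_equal(ls$ai_at_plateau, 476.46, tolerance = 1e-3)
  expect_equal(ls$duration_li_s, pl$t_plateau_s - ft$time_s[1])
  expect_lt(abs(ls$duration_lsi_s - 20), 0.01)
})

test_that("summary fields match generator-side recomputation", {
  p <- trace_params(duration_s = 25, cf_mean_g = 18, cf_sd_g = 0,
                    li0_ohm = 150, drop_ohm = 30, tau_drop_s = 5,
                    rebound_ohm_per_s = 0.5, noise_sd_ohm = 0, seed = 12)
  tr <- simulate_trace(p)
  cs <- test_constants()
  les <- process_cohort(list(tr), constants = cs)
  # independent recomputation from the closed-form generator params
  tstar <- noiseless_li_minimum(p)
  expect_lt(abs(les$duration_li_s + 0.75 - tstar), 0.08)
  expect_equal(les$cf_mean_g, 18, tolerance = 1e-6)
  # noiseless AI under constant CF/P has the closed form K*(CF^a P^b tau)^c
  d_ai <- (400 / cs$ai$K)^(1 / cs$ai$c) / (18^cs$ai$a * 40^cs$ai$b)
  expect_lt(abs(les$duration_ai_s - d_ai), 0.01)
  expect_true(is.na(les$ild_mm))
})
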