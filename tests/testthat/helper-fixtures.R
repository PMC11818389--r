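# Shared fixtures and independent oracles used across the test files.

# small calibrated constants used by most fixtures
test_constants <- function() default_metric_constants()

# uniform-grid trace data frame built directly (bypasses the generator)
make_uniform_trace <- function(time_s, li, cf = rep(15, length(time_s)),
                               power = rep(40, length(time_s)),
                               lesion_id = "L1", procedure_id = "P1") {
  out <- data.frame(procedure_id = procedure_id, lesion_id = lesion_id,
                    time_s = time_s, cf_g = cf, power_w = power, li_ohm = li,
                    x_mm = 0, y_mm = 0, z_mm = 0, stringsAsFactors = FALSE)
  class(out) <- c("ablation_trace", "data.frame")
  out
}

# brute-force all-pairs nearest-neighbour scan (independent ILD oracle)
ild_bruteforce <- function(positions) {
  out <- rep(NA_real_, nrow(positions))
  for (i in seq_len(nrow(positions))) {
    best <- Inf
    for (j in seq_len(nrow(positions))) {
      if (i == j) next
      if (positions$procedure_id[j] != positions$procedure_id[i]) next
      d <- sqrt((positions$x_mm[i] - positions$x_mm[j])^2 +
                  (positions$y_mm[i] - positions$y_mm[j])^2 +
                  (positions$z_mm[i] - positions$z_mm[j])^2)
      if (d < best) best <- d
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}

# hand-rolled Friedman statistic: 12n/(k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2
friedman_bruteforce <- function(M) {
  ranks <- t(apply(M, 1L, rank))
  k <- ncol(M); n <- nrow(M)
  rbar <- colMeans(ranks)
  12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
}

# exact signed-rank null distribution by enumeration of all 2^n sign vectors
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  # two-sided p: probability of |W - mu| at least as extreme
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-12)
}

# MAR lesion-summary fixture with a linear ground-truth LSI duration
make_mar_fixture <- function(seed, n = 300, rate = 0.25) {
  set.seed(seed)
  tab <- data.frame(
    duration_li_s = stats::rlnorm(n, log(12), 0.4),
    duration_ai_s = stats::rlnorm(n, log(7.3), 0.35),
    cf_mean_g = stats::rlnorm(n, log(18), 0.4),
    li_drop_ohm = stats::rlnorm(n, log(20), 0.35),
    li_start_ohm = stats::rnorm(n, 147, 9))
  tab$duration_lsi_s <- 10 + 0.4 * tab$duration_li_s - 0.25 * tab$cf_mean_g +
    0.15 * tab$li_drop_ohm + stats::rnorm(n, 0, 1)
  inject_missingness(tab, missingness_spec("MAR", rate, "cf_mean_g",
                                           seed = seed + 1L))
}

# cached mid-size cohort shared by processing-level tests
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(2, layout = procedure_layout(n_lesions = 15),
                                seed = 404)
    }
    cache
  }
})
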