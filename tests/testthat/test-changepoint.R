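# Exponential-fit change-point estimation.

planted_decay <- function(t, t0 = 80, tau = 80, base = 8, peak = 40) {
  ifelse(t < t0, peak, base + (peak - base) * exp(-(t - t0) / tau))
}

planted_rise <- function(t, t0 = 70, tau = 30, base = 8, peak = 40) {
  ifelse(t < t0, base, peak - (peak - base) * exp(-(t - t0) / tau))
}

test_that("noiseless planted transitions are recovered within 2 ms", {
  t <- seq(-250, 249)
  d <- estimate_decay_time(planted_decay(t), times = t)
  expect_true(d$ok)
  expect_lte(abs(d$time - 80), 2)
  expect_equal(d$kind, "decay")
  r <- estimate_rise_time(planted_rise(t), times = t, baseline = 8)
  expect_true(r$ok)
  expect_lte(abs(r$time - 70), 2)
  # the planted change point lies inside the fluctuation period
  expect_true(d$fluctuation[1] <= 80 && 80 <= d$fluctuation[2])
  expect_true(r$fluctuation[1] <= 70 && 70 <= r$fluctuation[2])
})

test_that("degenerate traces report structured no-changepoint results", {
  t <- seq(-250, 249)
  flat <- estimate_decay_time(rep(5, 500), times = t)
  expect_false(flat$ok)
  expect_true(is.na(flat$time))
  expect_false(estimate_rise_time(rep(5, 500), times = t)$ok)
  # monotone increasing trace has no decay
  expect_false(estimate_decay_time(seq(1, 50, length.out = 500), times = t)$ok)
})

test_that("the selected start matches an exhaustive candidate scan", {
  t <- seq(-250, 249)
  withr::with_seed(3, {
    y <- planted_decay(t, t0 = 60, tau = 60) + rnorm(500, 0, 1.5)
  })
  fit <- estimate_decay_time(y, times = t)
  expect_true(fit$ok)
  # independent exhaustive scan over the reported fluctuation period
  cand <- which(t >= fit$fluctuation[1] & t <= fit$fluctuation[2])
  end_idx <- which(t == fit$end_time)
  mses <- vapply(cand, function(s) {
    if (end_idx - s + 1 < 8) return(NA_real_)
    f <- fit_exponential(t[s:end_idx], y[s:end_idx])
    if (is.null(f)) NA_real_ else f$residual
  }, numeric(1))
  expect_equal(fit$time, t[cand[which.min(mses)]])
})

test_that("estimated change times are invariant to uniform rate scaling", {
  t <- seq(-250, 249)
  withr::with_seed(5, {
    y <- planted_decay(t, t0 = 75, tau = 50) + rnorm(500, 0, 1)
  })
  a <- estimate_decay_time(y, times = t)
  b <- estimate_decay_time(5 * y, times = t)
  expect_equal(a$time, b$time)
})

test_that("change times are recovered from Poisson trains at study scale", {
  cfg <- generator_config(n_pps_neurons = 6, n_lps_neurons = 6,
                          n_trials_per_direction = 60, rng_seed = 42)
  gs <- cached_session("changepoint", cfg)
  td <- cached_detection("changepoint", cfg)
  gtn <- gs$ground_truth$neurons
  err <- vapply(seq_len(nrow(gtn)), function(j) {
    nid <- gtn$neuron_id[j]
    pref <- gtn$preferred_direction[j]
    ok <- td[td$passed & td$direction == pref, ]
    dens <- neuron_aligned_density(gs$session, nid, ok)
    if (gtn$kind[j] == "PPS") {
      estimate_decay_time(dens)$time - gtn$decay_time[j]
    } else {
      estimate_rise_time(dens)$time - gtn$rise_time[j]
    }
  }, numeric(1))
  expect_true(all(is.finite(err)))
  expect_lt(sqrt(mean(err^2)), 35) # per-neuron scatter at small n
  expect_lt(abs(mean(err)), 20)
})

test_that("middle points interpolate between plateau and extreme", {
  # linear ramp 0 -> 1 over [0, 100]
  t <- 0:100
  expect_equal(middle_point_of_change(t / 100, times = t), 50)
  # step function crosses at the step
  y <- c(rep(0, 50), rep(1, 50))
  mid <- middle_point_of_change(y, times = 0:99)
  expect_lte(abs(mid - 49.5), 0.5)
  # decaying trace
  yd <- planted_decay(seq(-250, 249), t0 = 60, tau = 45)
  middec <- middle_point_of_change(yd, times = seq(-250, 249), kind = "decay")
  expect_equal(middec, 60 + 45 * log(2), tolerance = 1)
  expect_error(middle_point_of_change(rep(1, 100)), "crossing")
})

test_that("LPS activity rises before PPS activity decays at population level", {
  cfg <- generator_config(n_pps_neurons = 12, n_lps_neurons = 8,
                          n_trials_per_direction = 40, rng_seed = 77)
  gs <- cached_session("middlepoint", cfg)
  td <- cached_detection("middlepoint", cfg)
  gtn <- gs$ground_truth$neurons
  pop_trace <- function(kind) {
    rows <- which(gtn$kind == kind)
    traces <- lapply(rows, function(j) {
      pref <- gtn$preferred_direction[j]
      ok <- td[td$passed & td$direction == pref, ]
      neuron_aligned_density(gs$session, gtn$neuron_id[j], ok)$mean
    })
    population_average(traces)$mean
  }
  t <- seq(-250, 249)
  mid_pps <- middle_point_of_change(pop_trace("PPS"), times = t, kind = "decay")
  mid_lps <- middle_point_of_change(pop_trace("LPS"), times = t, kind = "rise")
  expect_lt(mid_lps, mid_pps)
})
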