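# Synthetic-session generator.

base_spec <- function(end = 10, latency = 180, duration = 40,
                      secondary = NULL) {
  list(direction = "right", fp_offset = 1600, latency = latency,
       duration = duration, end_x = end, end_y = 0, fix_x = 0, fix_y = 0,
       drift = 0, secondary = secondary, must_pass = TRUE)
}

test_that("generated eye traces land where told", {
  cfg <- generator_config(rng_seed = 1)
  withr::with_seed(5, {
    tr <- generate_eye_trace(base_spec(end = 10), cfg)
  })
  t <- seq_along(tr$x) - 1
  landing <- mean(tr$x[t >= tr$offset & t < tr$offset + 20])
  expect_equal(landing, 10, tolerance = 0.01)
  expect_equal(tr$offset - tr$onset, 40)
})

test_that("minimum-jerk peak speed matches its closed form", {
  cfg <- generator_config(eye_noise_sd = 0, rng_seed = 1)
  tr <- generate_eye_trace(base_spec(end = 9, duration = 40), cfg)
  v <- abs(diff(tr$x)) * 1000
  expect_equal(max(v), minjerk_peak_velocity(9, 40), tolerance = 0.01)
  # dense numeric maximisation of the analytic profile agrees
  tau <- seq(0, 1, by = 1e-5)
  vel <- 9 / 0.040 * 30 * tau^2 * (1 - tau)^2
  expect_equal(max(vel), minjerk_peak_velocity(9, 40), tolerance = 1e-6)
})

test_that("amplitude filter guard rejects sub-4-degree must-pass specs", {
  cfg <- generator_config(rng_seed = 1)
  expect_error(generate_eye_trace(base_spec(end = 3.5), cfg), "must_pass")
})

test_that("PPS rate profile follows its piecewise contract", {
  params <- list(baseline_rate = 8, peak_rate = 40, decay_time = 74.8,
                 decay_tau = 45, error_gain = 4)
  pref0 <- list(preferred = TRUE, duration = 40, error_signal = 0)
  # far before the ramp: baseline
  expect_equal(pps_rate_profile(-500, pref0, params), 8)
  # null direction stays at baseline throughout
  null_tr <- list(preferred = FALSE, duration = 40, error_signal = 2)
  expect_equal(pps_rate_profile(seq(-300, 400), null_tr, params),
               rep(8, 701))
  # zero error leaves the pure decayed profile at t = 250
  expect_equal(pps_rate_profile(250, pref0, params),
               8 + 32 * exp(-(250 - 74.8) / 45))
  # error term is linear in the error signal at t = 250
  r1 <- pps_rate_profile(250, modifyList(pref0, list(error_signal = 0.5)), params)
  r2 <- pps_rate_profile(250, modifyList(pref0, list(error_signal = 1.5)), params)
  expect_equal(r2 - r1, params$error_gain * 1.0)
  # perisaccadic rate does not depend on the error signal / end position
  peri <- seq(-150, 99)
  expect_equal(
    pps_rate_profile(peri, modifyList(pref0, list(error_signal = 2)), params),
    pps_rate_profile(peri, pref0, params))
})

test_that("LPS rate profile is silent pre-saccadically and position-tuned", {
  params <- list(baseline_rate = 8, peak_rate = 40, rise_time = 70.9,
                 rise_ramp = 20, position_gain = 8, target_eccentricity = 10)
  tr <- function(end) list(preferred = TRUE, end_motor = end)
  expect_equal(lps_rate_profile(-100, tr(10), params), 8)
  # sustained level difference = 2 * gain for end positions 9 vs 11
  d <- lps_rate_profile(150, tr(11), params) - lps_rate_profile(150, tr(9), params)
  expect_equal(d, 2 * params$position_gain)
  # null direction below preferred at the same time
  null_tr <- list(preferred = FALSE, end_motor = 10)
  expect_lt(lps_rate_profile(150, null_tr, params),
            lps_rate_profile(150, tr(10), params))
})

test_that("thinning sampler has the right mean and rejects bad rates", {
  withr::with_seed(7, {
    counts <- replicate(500, length(sample_spikes(function(t) {
      rep(20, length(t))
    }, 1000, rate_max = 20)))
  })
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 20), 3 * sem)
  expect_identical(sample_spikes(function(t) rep(0, length(t)), 1000), numeric(0))
  expect_error(sample_spikes(function(t) rep(-1, length(t)), 5000, rate_max = 5),
               "negative")
})

test_that("thinning agrees with a time-rescaling oracle", {
  ramp <- function(t) 10 + 40 * t / 1000 # 10 -> 50 spikes/s over 1 s
  withr::with_seed(11, {
    thin <- unlist(replicate(300, sample_spikes(ramp, 1000, rate_max = 50),
                             simplify = FALSE))
    resc <- unlist(replicate(300, oracle_rescaling_sampler(ramp, 1000),
                             simplify = FALSE))
  })
  bins <- seq(0, 1000, by = 100)
  h1 <- hist(thin, breaks = bins, plot = FALSE)$counts
  h2 <- hist(resc, breaks = bins, plot = FALSE)$counts
  # per-bin agreement within sampling error (Poisson SE of the difference)
  z <- (h1 - h2) / sqrt(h1 + h2)
  expect_true(all(abs(z) < 4))
  expect_lt(abs(sum(h1) - sum(h2)) / sqrt(sum(h1) + sum(h2)), 4)
})

test_that("identical seeds give identical sessions", {
  cfg <- small_cfg()
  gs1 <- generate_session(cfg)
  gs2 <- generate_session(cfg)
  expect_identical(gs1, gs2)
})

test_that("ground truth is internally consistent with the emitted session", {
  gs <- cached_session("small", small_cfg())
  gt <- gs$ground_truth$trials
  expect_equal(gt$error, abs(gt$end_motor - 10))
  expect_equal(nrow(gt), length(gs$session$trials))
  expect_equal(nrow(gs$ground_truth$neurons), nrow(gs$session$neurons))
  # a trial's behaviour is unchanged when neurons are added
  gs_more <- generate_session(small_cfg(n_pps_neurons = 5))
  expect_identical(gs_more$session$trials[[3]]$eye, gs$session$trials[[3]]$eye)
  expect_identical(gs_more$session$trials[[3]]$spikes[["pps_001"]],
                   gs$session$trials[[3]]$spikes[["pps_001"]])
})

test_that("secondary-saccade probability follows the configured error coupling", {
  # slope > 0: probability increases monotonically across error-signal bins
  cfg <- generator_config(n_pps_neurons = 0, n_lps_neurons = 0,
                          n_trials_per_direction = 1000, rng_seed = 31)
  gt <- generate_session(cfg)$ground_truth$trials
  qs <- quantile(gt$error_signal, probs = seq(0, 1, length.out = 6))
  bin <- cut(gt$error_signal, unique(qs), include.lowest = TRUE)
  p_by_bin <- tapply(gt$has_secondary, bin, mean)
  expect_true(all(diff(p_by_bin) > 0))
  # slope = 0: frequency independent of error (chi-square across terciles)
  cfg0 <- generator_config(n_pps_neurons = 0, n_lps_neurons = 0,
                           n_trials_per_direction = 1000,
                           secondary_base_prob = 0.25,
                           secondary_prob_slope = 0, rng_seed = 32)
  gt0 <- generate_session(cfg0)$ground_truth$trials
  terc <- cut(gt0$error, quantile(gt0$error, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  p <- chisq.test(table(terc, gt0$has_secondary))$p.value
  expect_gt(p, 0.01)
})
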