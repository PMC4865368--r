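# Saccade detection and trial filters.

flat_trace <- function(n = 2500, x = 0, y = 0) {
  structure(list(t0 = 0, dt = 1, x = rep(x, n), y = rep(y, n)),
            class = "eye_trace")
}

test_that("speed computation matches analytic derivatives", {
  n <- 1000
  ramp <- structure(list(t0 = 0, dt = 1, x = 0.1 * (0:(n - 1)), y = rep(0, n)),
                    class = "eye_trace")
  v <- compute_velocity(ramp)
  expect_equal(v[50:950], rep(100, 901), tolerance = 1e-9)
  expect_equal(compute_velocity(flat_trace()), rep(0, 2500))
  expect_error(compute_velocity(flat_trace(n = 4)), "shorter")
})

test_that("speed peaks within 1 ms of the analytic profile peak", {
  cfg <- generator_config(eye_noise_sd = 0, rng_seed = 1)
  spec <- list(direction = "right", fp_offset = 1600, latency = 200,
               duration = 40, end_x = 10, end_y = 0, fix_x = 0, fix_y = 0,
               drift = 0, secondary = NULL, must_pass = TRUE)
  tr <- generate_eye_trace(spec, cfg)
  v <- compute_velocity(tr)
  t_peak <- which.max(v) - 1
  expect_lte(abs(t_peak - (1800 + 20)), 1) # min-jerk peak at mid-saccade
})

test_that("detectors equal the brute-force threshold-scan oracle", {
  gs <- cached_session("small", small_cfg())
  for (tr in gs$session$trials) {
    speed <- compute_velocity(tr$eye)
    fp <- tr$events[["fp_offset"]]
    sac <- detect_primary_saccade(tr$eye, fp, speed = speed)
    orc <- oracle_primary(tr$eye, fp, speed)
    expect_equal(sac$onset, orc$onset)
    expect_equal(sac$offset, orc$offset)
    secs <- detect_secondary_saccades(tr$eye, sac, speed = speed)
    orcs <- oracle_secondary(tr$eye, sac$offset, speed)
    expect_equal(length(secs), length(orcs))
    if (length(secs) > 0) {
      expect_equal(vapply(secs, `[[`, 0, "onset"),
                   vapply(orcs, `[[`, 0, "onset"))
      expect_equal(vapply(secs, `[[`, 0, "offset"),
                   vapply(orcs, `[[`, 0, "offset"))
    }
  }
})

test_that("a flat trace yields no saccade and the trial fails with reason", {
  tr <- flat_trace()
  sac <- detect_primary_saccade(tr, 1600)
  expect_null(sac)
  out <- apply_trial_filters(sac, c(10, 0))
  expect_false(out$passed)
  expect_identical(out$failed_rules, "no_saccade")
})

test_that("trial filters apply the published bounds with strict boundaries", {
  # duration outside 10-100 ms (inclusive bounds)
  expect_identical(apply_trial_filters(make_saccade(duration = 8), c(10, 0))$failed_rules,
                   "duration")
  expect_true(apply_trial_filters(make_saccade(duration = 10), c(10, 0))$passed)
  expect_true(apply_trial_filters(make_saccade(duration = 100), c(10, 0))$passed)
  # amplitude exactly 4 fails the strict "larger than 4 degrees"
  expect_identical(apply_trial_filters(make_saccade(amplitude = 4), c(10, 0))$failed_rules,
                   "amplitude")
  # latency exactly 500 fails the strict "< 500 ms"
  expect_identical(apply_trial_filters(make_saccade(latency = 500), c(10, 0))$failed_rules,
                   "latency")
  # end point outside the 5-degree square window
  expect_identical(apply_trial_filters(make_saccade(end_x = 12.6), c(10, 0))$failed_rules,
                   "window")
  # circular window option
  far <- make_saccade(end_x = 12, end_y = 2)
  expect_true(apply_trial_filters(far, c(10, 0), window_shape = "square")$passed)
  expect_false(apply_trial_filters(far, c(10, 0), window_shape = "circular")$passed)
})

test_that("a planted fixture set passes and fails exactly as constructed", {
  cases <- list(
    list(s = make_saccade(), fail = character(0)),
    list(s = make_saccade(duration = 8), fail = "duration"),
    list(s = make_saccade(duration = 120), fail = "duration"),
    list(s = make_saccade(end_x = 13), fail = "window"),
    list(s = make_saccade(end_y = 3), fail = "window"),
    list(s = make_saccade(amplitude = 3.2), fail = "amplitude"),
    list(s = make_saccade(latency = 520), fail = "latency"),
    list(s = make_saccade(end_x = 9.4), fail = character(0)),
    list(s = NULL, fail = "no_saccade"),
    list(s = make_saccade(end_y = 1.5), fail = character(0)),
    list(s = make_saccade(duration = 55), fail = character(0)))
  outcomes <- lapply(cases, function(cs) apply_trial_filters(cs$s, c(10, 0)))
  expect_equal(sum(vapply(outcomes, `[[`, TRUE, "passed")), 4)
  for (k in seq_along(cases)) {
    expect_identical(outcomes[[k]]$failed_rules, cases[[k]]$fail)
  }
})

test_that("planted corrective saccades are recovered; early events excluded", {
  cfg <- generator_config(eye_noise_sd = 0.005, rng_seed = 3)
  spec <- list(direction = "right", fp_offset = 1600, latency = 200,
               duration = 40, end_x = 9, end_y = 0, fix_x = 0, fix_y = 0,
               drift = 0, must_pass = TRUE,
               secondary = list(latency = 154, end_x = 10, end_y = 0,
                                duration = 18))
  withr::with_seed(9, tr <- generate_eye_trace(spec, cfg))
  sac <- detect_primary_saccade(tr, 1600)
  secs <- detect_secondary_saccades(tr, sac)
  expect_length(secs, 1)
  expect_lte(abs(secs[[1]]$onset - tr$secondary_onset), 5)
  expect_gte(secs[[1]]$latency, 100)
  # the same event planted 60 ms after the primary offset is excluded
  spec$secondary$latency <- 60
  withr::with_seed(9, tr2 <- generate_eye_trace(spec, cfg))
  expect_length(detect_secondary_saccades(tr2, detect_primary_saccade(tr2, 1600)), 0)
})

test_that("detection is robust to small position noise", {
  spec <- list(direction = "right", fp_offset = 1600, latency = 200,
               duration = 40, end_x = 9.5, end_y = 0, fix_x = 0, fix_y = 0,
               drift = 0, secondary = NULL, must_pass = TRUE)
  clean <- generate_eye_trace(spec, generator_config(eye_noise_sd = 0, rng_seed = 1))
  ref <- detect_primary_saccade(clean, 1600)
  withr::with_seed(21, {
    for (k in 1:10) {
      noisy <- clean
      noisy$x <- clean$x + rnorm(length(clean$x), 0, 0.02)
      noisy$y <- clean$y + rnorm(length(clean$y), 0, 0.02)
      sac <- detect_primary_saccade(noisy, 1600)
      expect_lte(abs(sac$onset - ref$onset), 2)
      expect_lte(abs(sac$offset - ref$offset), 2)
    }
  })
})

test_that("session-level detection passes nearly all generated trials", {
  gs <- cached_session("small", small_cfg())
  td <- cached_detection("small", small_cfg())
  expect_equal(nrow(td), length(gs$session$trials))
  expect_gte(mean(td$passed), 0.95)
  gt <- gs$ground_truth$trials
  expect_true(all(abs(td$end_motor - gt$end_motor) < 0.05))
  expect_identical(td$has_secondary, gt$has_secondary)
})
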