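# Comparator analyses: binning, correlations, reference subtraction,
# piecewise fits and the subtraction model.

# hand-made binned_activity on a fixed grid
make_binned <- function(edges, means, counts = NULL) {
  k <- length(edges) - 1
  if (is.null(counts)) counts <- rep(100L, k)
  structure(data.frame(lo = edges[-length(edges)], hi = edges[-1],
                       center = (edges[-length(edges)] + edges[-1]) / 2,
                       n = counts, mean = means, sem = NA_real_),
            edges = edges, class = c("binned_activity", "data.frame"))
}

test_that("saccadic error is the absolute horizontal miss", {
  expect_equal(saccadic_error(10, 10), 0)
  expect_equal(saccadic_error(9.2, 10), 0.8)
  gs <- cached_session("small", small_cfg())
  gt <- gs$ground_truth$trials
  expect_equal(saccadic_error(gt$end_motor, 10), gt$error)
})

test_that("equal-width binning distributes evenly spaced positions evenly", {
  pos <- seq(-3, 3 - 1e-9, length.out = 1600)
  edges <- seq(-3, 3, length.out = 17)
  b <- bin_by_end_position(pos, rep(1, 1600), edges = edges)
  expect_equal(nrow(b), 16)
  expect_true(all(abs(b$n - 100) <= 2))
  expect_equal(sum(b$n), 1600)
})

test_that("degenerate and unimodal position sets bin sensibly", {
  b1 <- bin_by_end_position(rep(9.5, 50), rnorm(50), n_bins = 16)
  expect_equal(max(b1$n), 50) # all trials in one merged bin
  withr::with_seed(3, pos <- rnorm(4000, 9.66, 0.49))
  b2 <- bin_by_end_position(pos, rep(0, 4000), n_bins = 16)
  centermost <- order(abs(b2$center - 9.66))[1:2]
  expect_true(all(b2$n[centermost] >= max(b2$n[-centermost])))
  expect_error(bin_by_end_position(1:3, 1:2), "length")
})

test_that("small bins are merged with their neighbours", {
  pos <- c(rep(1, 3), rep(5, 50), rep(9, 3)) # sparse tails
  b <- bin_by_end_position(pos, seq_along(pos), n_bins = 8, min_trials = 5)
  expect_true(all(b$n >= 5))
  expect_equal(sum(b$n), length(pos))
})

test_that("single-trial correlations behave on exact and null data", {
  df <- data.frame(neuron_id = rep(c("a", "b"), each = 40),
                   x = rep(seq(8, 11, length.out = 40), 2))
  df$activity <- 2 * df$x
  ct <- single_trial_correlation(df)
  expect_equal(ct$per_neuron$r, c(1, 1))
  expect_equal(ct$mean_r, 1)
  # independent streams: population mean r near zero
  withr::with_seed(41, {
    null_df <- data.frame(neuron_id = rep(sprintf("n%02d", 1:50), each = 60),
                          activity = rnorm(3000), x = rnorm(3000))
  })
  ct0 <- single_trial_correlation(null_df)
  expect_lt(abs(ct0$mean_r), 0.05)
  # zero-variance neurons are excluded and reported
  bad <- rbind(df, data.frame(neuron_id = "flat", x = seq(8, 11, length.out = 40),
                              activity = 1))
  ct2 <- single_trial_correlation(bad)
  expect_identical(ct2$excluded, "flat")
  expect_equal(ct2$n_neurons, 2)
})

test_that("reference subtraction zeroes the target bin and is idempotent", {
  edges <- seq(8, 12, by = 0.5)
  b <- make_binned(edges, means = seq(0.4, 1.8, by = 0.2))
  rn <- reference_normalize(b, target = 10)
  hit <- which(b$lo <= 10 & 10 < b$hi)
  expect_equal(rn$mean[hit], 0)
  expect_equal(rn$mean, b$mean - b$mean[hit])
  expect_equal(reference_normalize(rn, 10)$mean, rn$mean)
  # constant activity becomes all zeros
  bc <- make_binned(edges, means = rep(1.3, 8))
  expect_equal(reference_normalize(bc, 10)$mean, rep(0, 8))
  expect_error(reference_normalize(b, target = 20), "no populated bin")
})

test_that("piecewise fits recover planted V shapes and straight lines", {
  edges <- seq(7, 13, by = 0.5)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  v <- make_binned(edges, means = abs(centers - 10))
  fit <- piecewise_linear_fit(v, split_at = 10)
  expect_equal(fit$lower$slope, -1, tolerance = 1e-8)
  expect_equal(fit$upper$slope, 1, tolerance = 1e-8)
  lin <- make_binned(edges, means = 0.3 * centers - 1)
  fit2 <- piecewise_linear_fit(lin, split_at = 10)
  expect_equal(fit2$lower$slope, fit2$upper$slope, tolerance = 1e-8)
  # a side without enough bins is reported absent
  short <- make_binned(edges, means = abs(centers - 10))
  fit3 <- piecewise_linear_fit(short, split_at = 7.2)
  expect_null(fit3$lower)
})

test_that("the subtraction model reduces to algebra on exact inputs", {
  edges <- seq(8, 12, by = 0.25)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  pps_flat <- make_binned(edges, means = rep(0, length(centers)))
  lps_lin <- make_binned(edges, means = 0.2 * (centers - 10))
  observed <- make_binned(edges, means = 0.2 * abs(centers - 10))
  sm <- subtraction_model(pps_flat, lps_lin, observed)
  expect_equal(sm$predicted, 0.2 * abs(centers - 10), tolerance = 1e-8)
  expect_lt(sm$agreement_rms, 1e-8)
  # degenerate position gain: prediction collapses to the flat PPS fit
  lps_zero <- make_binned(edges, means = rep(0, length(centers)))
  sm0 <- subtraction_model(pps_flat, lps_zero, lps_zero)
  expect_true(all(abs(sm0$predicted) < 1e-10))
  # mismatched grids refuse to combine
  other <- make_binned(seq(8, 12, by = 0.5), rep(0, 8))
  expect_error(subtraction_model(pps_flat, lps_lin, other), "common bin grid")
})

test_that("sliding-window correlation localises a planted error signal", {
  # hand-built session: 25 neurons whose rate carries error information only
  # inside [200, 300) ms after the (nominal) saccade end at t = 1000
  ev <- c(fixation_onset = 100, target_onset = 600, cue_on = 1000,
          cue_off = 1200, fp_offset = 1600)
  eye <- structure(list(t0 = 0, dt = 1, x = rep(0, 2000), y = rep(0, 2000)),
                   class = "eye_trace")
  n_tr <- 50
  n_neu <- 25
  withr::with_seed(67, {
    errs <- abs(rnorm(n_tr, 0, 0.5))
    trials <- lapply(seq_len(n_tr), function(i) {
      spikes <- lapply(seq_len(n_neu), function(j) {
        rate <- function(t) 10 + 25 * errs[i] * (t >= 1200 & t < 1300)
        sort(sample_spikes(rate, 2000, rate_max = 10 + 25 * errs[i]))
      })
      names(spikes) <- sprintf("n%02d", seq_len(n_neu))
      new_trial(i, "right", c(10, 0), ev, eye, spikes)
    })
  })
  s <- new_session("planted", trials = trials,
                   neurons = data.frame(neuron_id = sprintf("n%02d", seq_len(n_neu))))
  td <- data.frame(trial_id = seq_len(n_tr), direction = "right",
                   onset = 960, offset = 1000, passed = TRUE,
                   error = errs, fixation_onset = 100, fp_offset = 1600,
                   stringsAsFactors = FALSE)
  nd <- data.frame(neuron_id = sprintf("n%02d", seq_len(n_neu)),
                   preferred_direction = "right", stringsAsFactors = FALSE)
  sw <- sliding_window_error_correlation(s, td, nd, min_trials = 30)
  sig <- sw[sw$p < 0.001 & sw$mean_r > 0, ]
  expect_gt(nrow(sig), 0)
  # every significant window overlaps the planted [200, 300) epoch
  expect_true(all(sig$t_mid + 50 > 200 & sig$t_mid - 50 < 300))
  # windows far from the planted epoch carry no signal
  far <- sw[sw$t_mid < 120 | sw$t_mid > 400, ]
  expect_true(all(far$p > 0.001 | far$mean_r < 0))
})
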