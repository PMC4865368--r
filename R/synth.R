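# Synthetic-session generator.
#
# Emulates a two-target (left/right, +-eccentricity) delayed saccade task at
# 1 kHz: the monkey fixates, two targets appear, a spatial cue flags one of
# them, the fixation point goes off and a single primary saccade is made to
# the cued target, sometimes followed by a small corrective (secondary)
# saccade. Spike trains are inhomogeneous-Poisson realisations of PPS
# (persistent peri-saccadic), LPS (late post-saccadic) or featureless null
# rate profiles, so every downstream estimator can be validated against known
# ground truth.

# Fixed task timeline (ms from trial start). Fixation is attained at 100 ms,
# targets appear 500 ms later, the cue flashes for 200 ms after another
# 400 ms, and the fixation point is extinguished 400 ms after cue offset.
.task_events <- function() {
  c(fixation_onset = 100, target_onset = 600, cue_on = 1000,
    cue_off = 1200, fp_offset = 1600)
}

#' Configuration for the synthetic-session generator
#'
#' Defaults encode the study conditions: end positions are Gaussian around
#' the 10 degree target with mean 9.6615 and SD 0.4894 degrees; PPS activity
#' decays starting N(74.8, 33.1^2) ms after saccade completion; LPS activity
#' rises starting N(70.9, 31.3^2) ms after completion; corrective saccades
#' follow the primary one by ~154 ms on average.
#'
#' @param n_pps_neurons,n_lps_neurons,n_null_neurons number of neurons drawn
#'   from the PPS, LPS and unmodulated (null) generative arms.
#' @param n_trials_per_direction trials per target direction.
#' @param target_eccentricity horizontal target eccentricity, degrees.
#' @param endpoint_mean,endpoint_std mean and SD of the primary-saccade end
#'   position along the horizontal meridian, in motor coordinates (degrees).
#' @param pps_decay_mean_ms,pps_decay_std_ms population distribution of the
#'   true PPS decay time, ms after saccade end.
#' @param lps_rise_mean_ms,lps_rise_std_ms population distribution of the
#'   true LPS rise time, ms after saccade end.
#' @param lps_position_gain LPS sustained-rate slope, (spikes/s) per degree of
#'   horizontal end position.
#' @param pps_error_gain PPS late-epoch rate slope, (spikes/s) per degree of
#'   the trial's latent error signal (see `error_signal_noise_sd`). A free
#'   parameter of the model: the source recordings report only normalized
#'   correlations, never this gain.
#' @param error_signal_noise_sd SD of the zero-mean Gaussian noise added to
#'   the absolute saccadic error to form the latent per-trial error signal
#'   that drives both the PPS late-epoch term and the corrective-saccade
#'   decision (degrees).
#' @param secondary_base_prob,secondary_prob_slope corrective-saccade
#'   probability is `clamp(base + slope * error_signal, 0, 1)`.
#' @param secondary_latency_mean_ms,secondary_latency_sd_ms corrective-saccade
#'   latency after primary saccade end (clamped to [110, 300] ms so the
#'   100 ms exclusion rule can never reject a planted event).
#' @param secondary_away_frac fraction of corrective saccades directed away
#'   from the target (all secondary saccades count in the analyses).
#' @param baseline_rate,peak_rate baseline and peak firing rate, spikes/s.
#' @param pps_decay_tau_ms,lps_rise_ramp_ms time constants of the PPS
#'   exponential decay and of the LPS linear rise to its sustained level.
#' @param latency_mean_ms,latency_sd_ms primary-saccade latency draw
#'   (clamped to [100, 380] ms, within the 500 ms inclusion bound).
#' @param saccade_duration_range_ms uniform range of primary-saccade
#'   durations, ms.
#' @param eye_noise_sd additive white position noise, degrees.
#' @param fixation_jitter_sd SD of the per-trial fixation offset, degrees.
#' @param drift_sd SD of the zero-mean post-saccadic drift amplitude, degrees.
#' @param trace_length_ms eye-trace/trial length, ms.
#' @param rng_seed integer seed; identical seeds give identical sessions.
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_pps_neurons = 10,
                             n_lps_neurons = 5,
                             n_null_neurons = 0,
                             n_trials_per_direction = 60,
                             target_eccentricity = 10,
                             endpoint_mean = 9.6615,
                             endpoint_std = 0.4894,
                             pps_decay_mean_ms = 74.8,
                             pps_decay_std_ms = 33.1,
                             lps_rise_mean_ms = 70.9,
                             lps_rise_std_ms = 31.3,
                             lps_position_gain = 8,
                             pps_error_gain = 4,
                             error_signal_noise_sd = 0.25,
                             secondary_base_prob = 0.015,
                             secondary_prob_slope = 0.45,
                             secondary_latency_mean_ms = 154,
                             secondary_latency_sd_ms = 35,
                             secondary_away_frac = 0.15,
                             baseline_rate = 8,
                             peak_rate = 40,
                             pps_decay_tau_ms = 45,
                             lps_rise_ramp_ms = 20,
                             latency_mean_ms = 180,
                             latency_sd_ms = 40,
                             saccade_duration_range_ms = c(25, 60),
                             eye_noise_sd = 0.01,
                             fixation_jitter_sd = 0.05,
                             drift_sd = 0.01,
                             trace_length_ms = 2700,
                             rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_pps_neurons >= 0, cfg$n_lps_neurons >= 0, cfg$n_null_neurons >= 0,
    cfg$n_trials_per_direction >= 1,
    cfg$endpoint_std > 0,
    cfg$baseline_rate >= 0, cfg$peak_rate >= 0,
    cfg$lps_position_gain > 0, cfg$pps_error_gain >= 0,
    cfg$eye_noise_sd >= 0,
    length(cfg$saccade_duration_range_ms) == 2,
    cfg$trace_length_ms > 2400
  )
  cfg$secondary_base_prob <- clamp(cfg$secondary_base_prob, 0, 1)
  class(cfg) <- "generator_config"
  cfg
}

# Minimum-jerk unit displacement profile s(tau), tau in [0, 1].
# Closed form: s = 10 tau^3 - 15 tau^4 + 6 tau^5;
# ds/dtau = 30 tau^2 (1 - tau)^2, maximal at tau = 1/2 where it equals 15/8.
minjerk_pos <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

#' Analytic peak speed of a minimum-jerk saccade
#'
#' @param amplitude saccade amplitude, degrees.
#' @param duration_ms saccade duration, ms.
#' @return peak speed in degrees/s: `1.875 * amplitude / duration_s`.
#' @export
minjerk_peak_velocity <- function(amplitude, duration_ms) {
  1.875 * abs(amplitude) / (duration_ms / 1000)
}

#' Generate a single 1 kHz eye-position trace
#'
#' Builds a trial eye trace with stable fixation, a minimum-jerk primary
#' saccade to the prescribed end position, optional post-saccadic drift and
#' an optional corrective saccade, plus additive white position noise drawn
#' from the current RNG stream.
#'
#' @param trial_spec list with fields `direction` ("left"/"right"),
#'   `fp_offset` (ms), `latency` (ms after fp offset), `duration` (ms),
#'   `end_x`, `end_y` (degrees, signed screen coordinates), optional `fix_x`,
#'   `fix_y`, `drift`, `must_pass` and `secondary` (NULL, or a list with
#'   `latency` ms after primary saccade end, `end_x`, `end_y`, `duration`).
#' @param config a [generator_config()].
#' @return an object of class `eye_trace`: list with `t0`, `dt`, `x`, `y`
#'   plus generator ground truth `onset`, `offset` (primary saccade, ms) and
#'   `secondary_onset` (NA when absent).
#' @export
generate_eye_trace <- function(trial_spec, config) {
  ts <- trial_spec
  fix_x <- ts$fix_x %||% 0
  fix_y <- ts$fix_y %||% 0
  drift <- ts$drift %||% 0
  n <- config$trace_length_ms
  onset <- ts$fp_offset + ts$latency
  offset <- onset + ts$duration
  amp <- sqrt((ts$end_x - fix_x)^2 + (ts$end_y - fix_y)^2)
  if (isTRUE(ts$must_pass) && amp <= 4) {
    stop("trial_spec implies amplitude <= 4 degrees but is flagged must_pass")
  }
  if (offset + 650 > n) stop("trace too short for the requested saccade")
  t <- seq_len(n) - 1
  x <- rep(fix_x, n)
  y <- rep(fix_y, n)
  seg <- t >= onset & t < offset
  tau <- (t[seg] - onset) / ts$duration
  x[seg] <- fix_x + (ts$end_x - fix_x) * minjerk_pos(tau)
  y[seg] <- fix_y + (ts$end_y - fix_y) * minjerk_pos(tau)
  post <- t >= offset
  x[post] <- ts$end_x
  y[post] <- ts$end_y
  if (drift != 0) { # slow settling over 100 ms, then constant
    dseg <- t >= offset & t < offset + 100
    x[dseg] <- x[dseg] + drift * (t[dseg] - offset) / 100
    x[t >= offset + 100] <- ts$end_x + drift
  }
  sec_onset <- NA_real_
  if (!is.null(ts$secondary)) {
    sec <- ts$secondary
    sec_onset <- offset + sec$latency
    sec_off <- sec_onset + sec$duration
    if (sec_off + 50 > n) stop("trace too short for the secondary saccade")
    x0 <- x[floor(sec_onset)] # position when the corrective saccade starts
    y0 <- y[floor(sec_onset)]
    sseg <- t >= sec_onset & t < sec_off
    stau <- (t[sseg] - sec_onset) / sec$duration
    x[sseg] <- x0 + (sec$end_x - x0) * minjerk_pos(stau)
    y[sseg] <- y0 + (sec$end_y - y0) * minjerk_pos(stau)
    x[t >= sec_off] <- sec$end_x
    y[t >= sec_off] <- sec$end_y
  }
  if (config$eye_noise_sd > 0) {
    x <- x + stats::rnorm(n, 0, config$eye_noise_sd)
    y <- y + stats::rnorm(n, 0, config$eye_noise_sd)
  }
  structure(list(t0 = 0, dt = 1, x = x, y = y,
                 onset = onset, offset = offset, secondary_onset = sec_onset),
            class = "eye_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PPS firing-rate profile
#'
#' Piecewise rate profile of a persistent peri-saccadic neuron: baseline
#' until 200 ms before saccade onset, then a linear ramp that reaches
#' `peak_rate` at the neuron's true decay time after saccade end (activity
#' climbs until shortly after the saccade and then turns over), followed by
#' an exponential decay back toward baseline. During the 150-350 ms
#' post-saccadic epoch the rate is additionally elevated by
#' `error_gain * error_signal`, with raised-cosine edges (40 ms rise from
#' 150 ms, 40 ms fall to 350 ms) so the error signal emerges and fades
#' smoothly. The peri-saccadic rate never depends on the saccade end
#' position, and null-direction trials stay at baseline.
#'
#' @param t time, ms relative to primary saccade end (vectorised).
#' @param trial list with `preferred` (logical), `duration` (primary saccade
#'   duration, ms) and `error_signal` (degrees, >= 0).
#' @param params list with `baseline_rate`, `peak_rate`, `decay_time` (ms
#'   after saccade end), `decay_tau` and `error_gain`.
#' @return firing rate, spikes/s.
#' @export
pps_rate_profile <- function(t, trial, params) {
  base <- params$baseline_rate
  r <- rep(base, length(t))
  if (!isTRUE(trial$preferred)) return(r)
  onset <- -trial$duration
  peak <- params$peak_rate
  # the ramp tops out at the decay time (never earlier than just after onset)
  peak_t <- max(params$decay_time, onset + 5)
  ramp <- t >= onset - 200 & t < peak_t
  r[ramp] <- base + (peak - base) * (t[ramp] - (onset - 200)) /
    (peak_t - (onset - 200))
  dec <- t >= peak_t
  r[dec] <- base + (peak - base) * exp(-(t[dec] - peak_t) / params$decay_tau)
  err <- t >= 150 & t < 350
  te <- t[err]
  shape <- rep(1, length(te))
  up <- te < 190
  shape[up] <- 0.5 * (1 - cos(pi * (te[up] - 150) / 40))
  down <- te >= 310
  shape[down] <- 0.5 * (1 - cos(pi * (350 - te[down]) / 40))
  r[err] <- r[err] + params$error_gain * trial$error_signal * shape
  pmax(r, 0)
}

#' LPS firing-rate profile
#'
#' Late post-saccadic neuron: baseline until the neuron's true rise time
#' after saccade end, then a linear ramp (default 40 ms) to a sustained level
#' `peak_rate + position_gain * (end position - target eccentricity)`, both
#' in motor coordinates. There is no pre-saccadic modulation, and
#' null-direction trials stay at baseline.
#'
#' @param t time, ms relative to primary saccade end (vectorised).
#' @param trial list with `preferred` (logical) and `end_motor` (horizontal
#'   end position, motor coordinates, degrees).
#' @param params list with `baseline_rate`, `peak_rate`, `rise_time`,
#'   `rise_ramp`, `position_gain`, `target_eccentricity`.
#' @return firing rate, spikes/s.
#' @export
lps_rate_profile <- function(t, trial, params) {
  base <- params$baseline_rate
  r <- rep(base, length(t))
  if (!isTRUE(trial$preferred)) return(r)
  sus <- params$peak_rate +
    params$position_gain * (trial$end_motor - params$target_eccentricity)
  up <- t >= params$rise_time
  frac <- clamp((t[up] - params$rise_time) / params$rise_ramp, 0, 1)
  r[up] <- base + (sus - base) * frac
  pmax(r, 0)
}

#' Sample an inhomogeneous-Poisson spike train by thinning
#'
#' Candidate events are drawn from a homogeneous Poisson process at
#' `rate_max` and retained with probability `rate(t)/rate_max`. `rate_max`
#' must dominate the profile everywhere; by default it is taken as the
#' profile maximum on a 0.5 ms grid (exact for the piecewise profiles used
#' by the generator).
#'
#' @param rate_fn vectorised function of time (ms) returning spikes/s.
#' @param duration trial duration, ms.
#' @param rate_max optional dominating rate, spikes/s.
#' @return sorted spike times in ms within `[0, duration)`.
#' @export
sample_spikes <- function(rate_fn, duration, rate_max = NULL) {
  if (is.null(rate_max)) {
    rate_max <- max(rate_fn(seq(0, duration, by = 0.5)))
  }
  if (is.na(rate_max) || rate_max < 0) stop("negative or undefined rate bound")
  if (rate_max == 0) return(numeric(0))
  n_cand <- stats::rpois(1, rate_max * duration / 1000)
  if (n_cand == 0) return(numeric(0))
  tt <- sort(stats::runif(n_cand, 0, duration))
  r <- rate_fn(tt)
  if (any(r < 0)) stop("rate function returned a negative rate")
  if (any(r > rate_max * (1 + 1e-8))) {
    stop("rate function exceeds the supplied rate_max bound")
  }
  tt[stats::runif(n_cand) < r / rate_max]
}

# Draw the behavioural specification of one trial. Uses its own substream so
# the trial is reproducible independently of the neuron count.
.draw_trial <- function(i, direction, config) {
  set.seed(mix_seed(config$rng_seed, 101, i))
  ecc <- config$target_eccentricity
  dir_sign <- if (direction == "left") -1 else 1
  end_motor <- stats::rnorm(1, config$endpoint_mean, config$endpoint_std)
  end_y <- stats::rnorm(1, 0, config$endpoint_std)
  latency <- clamp(stats::rnorm(1, config$latency_mean_ms,
                                config$latency_sd_ms), 100, 380)
  duration <- stats::runif(1, config$saccade_duration_range_ms[1],
                           config$saccade_duration_range_ms[2])
  fix_x <- stats::rnorm(1, 0, config$fixation_jitter_sd)
  fix_y <- stats::rnorm(1, 0, config$fixation_jitter_sd)
  drift <- stats::rnorm(1, 0, config$drift_sd)
  error <- abs(end_motor - ecc)
  # noisy internal estimate of the error; may dip below zero (rates are
  # floored at zero in the profiles, the corrective-saccade probability is
  # clamped), so the estimate is conditionally unbiased in the error
  error_signal <- error + stats::rnorm(1, 0, config$error_signal_noise_sd)
  p_sec <- clamp(config$secondary_base_prob +
                   config$secondary_prob_slope * error_signal, 0, 1)
  has_secondary <- stats::runif(1) < p_sec
  secondary <- NULL
  sec_latency <- NA_real_
  sec_toward <- NA
  if (has_secondary) {
    sec_latency <- clamp(stats::rnorm(1, config$secondary_latency_mean_ms,
                                      config$secondary_latency_sd_ms), 110, 300)
    gain <- clamp(stats::rnorm(1, 0.9, 0.15), 0.5, 1.2)
    delta <- (ecc - end_motor) * gain # motor coordinates, toward target
    if (abs(delta) < 0.25) delta <- 0.25 * ifelse(delta < 0, -1, 1)
    sec_toward <- stats::runif(1) >= config$secondary_away_frac
    if (!sec_toward) delta <- -delta
    secondary <- list(latency = sec_latency,
                      end_x = dir_sign * (end_motor + delta),
                      end_y = end_y,
                      duration = stats::runif(1, 14, 24))
  }
  list(trial_id = i, direction = direction,
       target_x = dir_sign * ecc, target_y = 0,
       fp_offset = .task_events()[["fp_offset"]],
       latency = latency, duration = duration,
       end_x = dir_sign * end_motor, end_y = end_y, end_motor = end_motor,
       fix_x = fix_x, fix_y = fix_y, drift = drift,
       error = error, error_signal = error_signal,
       has_secondary = has_secondary, secondary_latency = sec_latency,
       secondary_toward = sec_toward, secondary = secondary,
       must_pass = TRUE)
}

# Draw neuron ground-truth parameters. The true class honours the 35 ms
# change-time bound that defines the PPS/LPS classes: a PPS-arm neuron whose
# drawn decay time is <= 35 ms is truly "neither".
.draw_neurons <- function(config) {
  rows <- list()
  for (j in seq_len(config$n_pps_neurons)) {
    set.seed(mix_seed(config$rng_seed, 201, j))
    decay <- stats::rnorm(1, config$pps_decay_mean_ms, config$pps_decay_std_ms)
    rows[[length(rows) + 1]] <- data.frame(
      neuron_id = sprintf("pps_%03d", j), kind = "PPS",
      true_class = if (decay > 35) "PPS" else "neither",
      preferred_direction = sample(c("right", "left"), 1),
      decay_time = decay, rise_time = NA_real_,
      position_gain = 0, error_gain = config$pps_error_gain,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(config$n_lps_neurons)) {
    set.seed(mix_seed(config$rng_seed, 202, j))
    rise <- stats::rnorm(1, config$lps_rise_mean_ms, config$lps_rise_std_ms)
    rows[[length(rows) + 1]] <- data.frame(
      neuron_id = sprintf("lps_%03d", j), kind = "LPS",
      true_class = if (rise > 35) "LPS" else "neither",
      preferred_direction = sample(c("right", "left"), 1),
      decay_time = NA_real_, rise_time = rise,
      position_gain = config$lps_position_gain, error_gain = 0,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(config$n_null_neurons)) {
    set.seed(mix_seed(config$rng_seed, 203, j))
    rows[[length(rows) + 1]] <- data.frame(
      neuron_id = sprintf("null_%03d", j), kind = "null",
      true_class = "neither",
      preferred_direction = sample(c("right", "left"), 1),
      decay_time = NA_real_, rise_time = NA_real_,
      position_gain = 0, error_gain = 0,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(neuron_id = character(0), kind = character(0),
                      true_class = character(0),
                      preferred_direction = character(0),
                      decay_time = numeric(0), rise_time = numeric(0),
                      position_gain = numeric(0), error_gain = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Rate profile of one neuron on one trial, in absolute trial time, plus the
# analytic dominating bound used by the thinning sampler.
.neuron_trial_rate <- function(neuron, trial, config) {
  preferred <- trial$direction == neuron$preferred_direction
  t_end <- trial$fp_offset + trial$latency + trial$duration
  if (neuron$kind == "PPS") {
    params <- list(baseline_rate = config$baseline_rate,
                   peak_rate = config$peak_rate,
                   decay_time = neuron$decay_time,
                   decay_tau = config$pps_decay_tau_ms,
                   error_gain = neuron$error_gain)
    tr <- list(preferred = preferred, duration = trial$duration,
               error_signal = trial$error_signal)
    fn <- function(t) pps_rate_profile(t - t_end, tr, params)
    bound <- if (preferred) {
      config$peak_rate + neuron$error_gain * max(trial$error_signal, 0)
    } else config$baseline_rate
  } else if (neuron$kind == "LPS") {
    params <- list(baseline_rate = config$baseline_rate,
                   peak_rate = config$peak_rate,
                   rise_time = neuron$rise_time,
                   rise_ramp = config$lps_rise_ramp_ms,
                   position_gain = neuron$position_gain,
                   target_eccentricity = config$target_eccentricity)
    tr <- list(preferred = preferred, end_motor = trial$end_motor)
    fn <- function(t) lps_rate_profile(t - t_end, tr, params)
    sus <- config$peak_rate + neuron$position_gain *
      (trial$end_motor - config$target_eccentricity)
    bound <- if (preferred) max(config$baseline_rate, sus) else config$baseline_rate
  } else {
    fn <- function(t) rep(config$baseline_rate, length(t))
    bound <- config$baseline_rate
  }
  list(fn = fn, bound = bound)
}

#' Generate a complete synthetic session with ground truth
#'
#' Draws the behavioural stream (trial specifications and eye traces), the
#' neuron population, and per-neuron/per-trial inhomogeneous-Poisson spike
#' trains. Randomness is split hierarchically into substreams keyed by the
#' session seed and trial/neuron indices, so a given trial's behaviour is
#' identical whatever the neuron count, and an identical seed reproduces the
#' session exactly.
#'
#' @param config a [generator_config()].
#' @return list with elements `session` (a [new_session()] object) and
#'   `ground_truth` (list of data frames `neurons`, one row per neuron, and
#'   `trials`, one row per trial).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$rng_seed, {
    n_dir <- config$n_trials_per_direction
    directions <- rep(c("right", "left"), n_dir)[seq_len(2 * n_dir)]
    specs <- lapply(seq_along(directions), function(i) {
      .draw_trial(i, directions[i], config)
    })
    neurons <- .draw_neurons(config)
    # kind-stable index so adding null neurons never reseeds PPS streams
    kind_code <- c(PPS = 1e6, LPS = 2e6, null = 3e6)
    trials <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      ts <- specs[[i]]
      set.seed(mix_seed(config$rng_seed, 102, i)) # trace-noise substream
      trace <- generate_eye_trace(ts, config)
      spikes <- list()
      if (nrow(neurons) > 0) {
        within_kind <- stats::ave(seq_len(nrow(neurons)),
                                  neurons$kind, FUN = seq_along)
        for (j in seq_len(nrow(neurons))) {
          nrn <- neurons[j, ]
          idx <- kind_code[[nrn$kind]] + within_kind[j]
          set.seed(mix_seed(config$rng_seed, 301, idx, i))
          prof <- .neuron_trial_rate(nrn, ts, config)
          spikes[[nrn$neuron_id]] <-
            sample_spikes(prof$fn, config$trace_length_ms,
                          rate_max = prof$bound)
        }
      }
      trials[[i]] <- new_trial(
        trial_id = ts$trial_id, direction = ts$direction,
        target = c(ts$target_x, ts$target_y),
        events = .task_events(),
        eye = trace, spikes = spikes)
    }
    session <- new_session(
      session_id = sprintf("synthetic_scs_seed%d", config$rng_seed),
      task = "SCS_horizontal", sampling_rate = 1000,
      trials = trials,
      neurons = data.frame(neuron_id = neurons$neuron_id,
                           stringsAsFactors = FALSE))
    gt_trials <- do.call(rbind, lapply(specs, function(ts) {
      tr <- trials[[ts$trial_id]]
      data.frame(trial_id = ts$trial_id, direction = ts$direction,
                 target_x = ts$target_x,
                 end_x = ts$end_x, end_y = ts$end_y,
                 end_motor = ts$end_motor,
                 error = ts$error, error_signal = ts$error_signal,
                 latency = ts$latency, duration = ts$duration,
                 true_onset = tr$eye$onset, true_offset = tr$eye$offset,
                 has_secondary = ts$has_secondary,
                 secondary_latency = ts$secondary_latency,
                 secondary_toward = ts$secondary_toward,
                 stringsAsFactors = FALSE)
    }))
    list(session = session,
         ground_truth = list(neurons = neurons, trials = gt_trials))
  })
}
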