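# Saccade detection and trial-inclusion filters.
#
# Detection operates on eye speed: positions are smoothed with a short boxcar
# (default 5 ms), differentiated by central differences, and thresholded.
# A primary saccade starts at the first sample after fixation-point offset
# whose speed exceeds 30 deg/s and ends at the first sample after the speed
# peak where speed falls below 10% of that peak. Secondary (corrective)
# saccades use an 8 deg/s onset threshold, must last more than 5 ms, exceed
# 0.2 deg amplitude, and start at least 100 ms after the primary saccade end.
# The template-matching criterion sometimes used alongside velocity
# thresholds is not implemented; velocity thresholds alone are applied.

#' Eye speed from a 1 kHz position trace
#'
#' Positions are smoothed with a boxcar of width `smooth_ms` (edges padded by
#' replication), then differentiated with a central difference over +-1
#' sample. Speed is the magnitude of the 2-D derivative, same length as the
#' input (edge samples copied from their neighbours).
#'
#' @param trace an `eye_trace`.
#' @param smooth_ms boxcar width in ms (odd values recommended; default 5).
#' @return numeric vector of speeds, degrees/s.
#' @export
compute_velocity <- function(trace, smooth_ms = 5) {
  n <- length(trace$x)
  w <- max(1L, as.integer(smooth_ms))
  if (n < w + 2) stop("trace shorter than the smoothing kernel")
  smooth <- function(z) {
    if (w == 1) return(z)
    k <- w %/% 2
    zp <- c(rep(z[1], k), z, rep(z[n], k))
    as.numeric(stats::filter(zp, rep(1 / w, w), sides = 2))[(k + 1):(k + n)]
  }
  xs <- smooth(trace$x)
  ys <- smooth(trace$y)
  cd <- function(z) {
    v <- c(NA, (z[3:n] - z[1:(n - 2)]) / 2, NA)
    v[1] <- v[2]
    v[n] <- v[n - 1]
    v
  }
  # dt = 1 ms, so deg/ms * 1000 = deg/s
  sqrt(cd(xs)^2 + cd(ys)^2) * 1000 / trace$dt
}

.trace_times <- function(trace) trace$t0 + (seq_along(trace$x) - 1) * trace$dt

# mean eye position over the half-open window [lo, lo + 20) ms
.end_position <- function(trace, t, lo, span = 20) {
  sel <- t >= lo & t < lo + span
  c(x = mean(trace$x[sel]), y = mean(trace$y[sel]))
}

.make_saccade <- function(trace, t, onset_i, offset_i, peak_vel, fp_offset) {
  end_pos <- .end_position(trace, t, t[offset_i])
  structure(list(
    onset = t[onset_i], offset = t[offset_i],
    duration = t[offset_i] - t[onset_i],
    amplitude = sqrt((trace$x[offset_i] - trace$x[onset_i])^2 +
                       (trace$y[offset_i] - trace$y[onset_i])^2),
    peak_velocity = peak_vel,
    latency = if (is.null(fp_offset)) NA_real_ else t[onset_i] - fp_offset,
    end_x = end_pos[["x"]], end_y = end_pos[["y"]]),
    class = "saccade")
}

#' Detect the primary saccade after fixation-point offset
#'
#' Onset is the first sample after `fp_offset` with speed above
#' `onset_threshold`; the peak is the maximum speed from onset until speed
#' first returns below the onset threshold; offset is the first sample after
#' the peak with speed below `offset_fraction` of the peak. The end position
#' is the mean eye position over 0-20 ms after the offset.
#'
#' @param trace an `eye_trace`.
#' @param fp_offset fixation-point offset time, ms.
#' @param search_window ms after `fp_offset` in which the onset must occur.
#' @param onset_threshold deg/s (default 30).
#' @param offset_fraction fraction of peak speed marking the offset (0.1).
#' @param speed optional precomputed speed vector from [compute_velocity()].
#' @return a `saccade` (list with onset, offset, duration, amplitude,
#'   peak_velocity, latency, end_x, end_y) or `NULL` when no saccade is found.
#' @export
detect_primary_saccade <- function(trace, fp_offset, search_window = 600,
                                   onset_threshold = 30,
                                   offset_fraction = 0.1, speed = NULL) {
  if (is.null(speed)) speed <- compute_velocity(trace)
  t <- .trace_times(trace)
  n <- length(t)
  cand <- which(t > fp_offset & t < fp_offset + search_window &
                  speed > onset_threshold)
  if (length(cand) == 0) return(NULL)
  onset_i <- cand[1]
  below <- which(speed[onset_i:n] < onset_threshold)
  seg_end <- if (length(below) == 0) n else onset_i + below[1] - 2
  peak_i <- onset_i + which.max(speed[onset_i:seg_end]) - 1
  peak_vel <- speed[peak_i]
  off_cand <- which(speed[(peak_i + 1):n] < offset_fraction * peak_vel)
  if (peak_i >= n || length(off_cand) == 0) return(NULL)
  offset_i <- peak_i + off_cand[1]
  if (t[offset_i] + 20 > t[n]) return(NULL)
  .make_saccade(trace, t, onset_i, offset_i, peak_vel, fp_offset)
}

#' Apply the trial-inclusion filters to a detected primary saccade
#'
#' A trial passes when the saccade duration is within 10-100 ms (inclusive),
#' the end point lies within a 5 degree window centred on the target, the
#' amplitude is strictly larger than 4 degrees, and the latency is strictly
#' below 500 ms. A missing saccade fails with reason `no_saccade`.
#'
#' @param saccade a `saccade` or `NULL`.
#' @param target_position numeric `c(x, y)`, degrees.
#' @param window_size full width of the end-point check window, degrees.
#' @param window_shape `"square"` (|dx| and |dy| each within half the window)
#'   or `"circular"` (Euclidean distance within half the window).
#' @return list with `passed` (logical) and `failed_rules` (character vector,
#'   subset of duration, window, amplitude, latency, no_saccade).
#' @export
apply_trial_filters <- function(saccade, target_position, window_size = 5,
                                window_shape = c("square", "circular")) {
  window_shape <- match.arg(window_shape)
  if (is.null(saccade)) {
    return(list(passed = FALSE, failed_rules = "no_saccade"))
  }
  failed <- character(0)
  if (saccade$duration < 10 || saccade$duration > 100) {
    failed <- c(failed, "duration")
  }
  half <- window_size / 2
  dx <- saccade$end_x - target_position[1]
  dy <- saccade$end_y - target_position[2]
  in_window <- if (window_shape == "square") {
    abs(dx) <= half && abs(dy) <= half
  } else {
    sqrt(dx^2 + dy^2) <= half
  }
  if (!in_window) failed <- c(failed, "window")
  if (!(saccade$amplitude > 4)) failed <- c(failed, "amplitude")
  if (!(saccade$latency < 500)) failed <- c(failed, "latency")
  list(passed = length(failed) == 0, failed_rules = failed)
}

#' Detect secondary (corrective) saccades
#'
#' Scans the trace after the primary saccade for events whose speed exceeds
#' `onset_threshold` (8 deg/s), keeping those with duration strictly greater
#' than `min_duration`, amplitude strictly greater than `min_amplitude`, and
#' onset at least `min_gap` ms after the primary saccade offset. Event
#' offsets follow the primary-saccade rule (first sample after the event's
#' speed peak below 10% of that peak). All qualifying events are returned,
#' whatever their direction.
#'
#' @param trace an `eye_trace`.
#' @param primary the detected primary `saccade`.
#' @param onset_threshold deg/s (default 8).
#' @param min_duration ms (default 5, strict).
#' @param min_amplitude degrees (default 0.2, strict).
#' @param min_gap ms after the primary saccade offset (default 100).
#' @param offset_fraction fraction of event peak speed marking its offset.
#' @param speed optional precomputed speed vector.
#' @return list of `saccade` objects (possibly empty); each has `latency`
#'   relative to the primary saccade offset.
#' @export
detect_secondary_saccades <- function(trace, primary, onset_threshold = 8,
                                      min_duration = 5, min_amplitude = 0.2,
                                      min_gap = 100, offset_fraction = 0.1,
                                      speed = NULL) {
  if (is.null(speed)) speed <- compute_velocity(trace)
  t <- .trace_times(trace)
  n <- length(t)
  out <- list()
  i <- which(t >= primary$offset + min_gap)[1]
  if (is.na(i)) return(out)
  while (i <= n) {
    rel <- which(speed[i:n] > onset_threshold)
    if (length(rel) == 0) break
    onset_i <- i + rel[1] - 1
    below <- which(speed[onset_i:n] < onset_threshold)
    seg_end <- if (length(below) == 0) n else onset_i + below[1] - 2
    peak_i <- onset_i + which.max(speed[onset_i:seg_end]) - 1
    peak_vel <- speed[peak_i]
    off_cand <- which(speed[(peak_i + 1):n] < offset_fraction * peak_vel)
    if (peak_i >= n || length(off_cand) == 0) break
    offset_i <- peak_i + off_cand[1]
    if (t[offset_i] + 20 <= t[n]) {
      sac <- .make_saccade(trace, t, onset_i, offset_i, peak_vel, NULL)
      sac$latency <- sac$onset - primary$offset
      if (sac$duration > min_duration && sac$amplitude > min_amplitude) {
        out[[length(out) + 1]] <- sac
      }
    }
    i <- offset_i + 1
  }
  out
}

#' Detect saccades and apply inclusion filters across a session
#'
#' Runs [detect_primary_saccade()], [apply_trial_filters()] and
#' [detect_secondary_saccades()] on every trial and assembles the per-trial
#' analysis table used by the downstream modules.
#'
#' @param session an `scs_session`.
#' @param ... passed to the detectors (thresholds, window shape).
#' @return data frame with one row per trial: detected saccade kinematics,
#'   end position in screen and motor coordinates, saccadic error (degrees,
#'   horizontal meridian), filter outcome and secondary-saccade summary.
#' @export
detect_saccades <- function(session, ...) {
  dots <- list(...)
  filt_args <- dots[names(dots) %in% c("window_size", "window_shape")]
  rows <- lapply(session$trials, function(tr) {
    speed <- compute_velocity(tr$eye)
    sac <- detect_primary_saccade(tr$eye, tr$events[["fp_offset"]],
                                  speed = speed)
    filt <- do.call(apply_trial_filters,
                    c(list(sac, tr$target), filt_args))
    secs <- if (is.null(sac)) list() else {
      detect_secondary_saccades(tr$eye, sac, speed = speed)
    }
    ecc <- abs(tr$target[1])
    end_motor <- if (is.null(sac)) NA_real_ else {
      motor_position(sac$end_x, tr$direction)
    }
    data.frame(
      trial_id = tr$trial_id, direction = tr$direction,
      target_x = tr$target[1], target_eccentricity = ecc,
      onset = sac$onset %||% NA_real_, offset = sac$offset %||% NA_real_,
      duration = sac$duration %||% NA_real_,
      amplitude = sac$amplitude %||% NA_real_,
      peak_velocity = sac$peak_velocity %||% NA_real_,
      latency = sac$latency %||% NA_real_,
      end_x = sac$end_x %||% NA_real_, end_y = sac$end_y %||% NA_real_,
      end_motor = end_motor,
      error = if (is.null(sac)) NA_real_ else abs(end_motor - ecc),
      passed = filt$passed,
      failed_rules = paste(filt$failed_rules, collapse = ";"),
      n_secondary = length(secs),
      has_secondary = length(secs) > 0,
      secondary_latency = if (length(secs)) secs[[1]]$latency else NA_real_,
      fixation_onset = tr$events[["fixation_onset"]],
      fp_offset = tr$events[["fp_offset"]],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
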