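# Spike-density estimation, epoch rates, baseline normalization and
# population averaging.

#' Named analysis epochs
#'
#' Half-open windows in ms, each bound to its alignment event. Two baseline
#' windows exist on purpose: classification uses [0, 500) and normalization
#' uses [100, 500) after fixation onset.
#'
#' @return named list of `list(window, align)` entries.
#' @export
epoch_windows <- function() {
  list(
    baseline_norm = list(window = c(100, 500), align = "fixation_onset"),
    baseline_class = list(window = c(0, 500), align = "fixation_onset"),
    pre_saccadic = list(window = c(-200, 0), align = "saccade_onset"),
    perisaccadic = list(window = c(-150, 100), align = "saccade_end"),
    early_post = list(window = c(0, 100), align = "saccade_end"),
    lps_tuning = list(window = c(25, 225), align = "saccade_end"),
    lps_corr = list(window = c(25, 125), align = "saccade_end"),
    post_subtraction = list(window = c(150, 350), align = "saccade_end")
  )
}

#' Gaussian-kernel spike density
#'
#' Sum of unit-area Gaussians (default sigma = 5 ms) centred on each spike,
#' evaluated exactly on the 1 ms trial grid and scaled to spikes/s. The
#' density integrates to the spike count except within ~5 sigma of the grid
#' edges, where kernel mass falls outside the grid.
#'
#' @param spike_times spike times, ms (sorted).
#' @param t0 grid start, ms.
#' @param n_samples grid length.
#' @param sigma kernel SD, ms.
#' @param dt grid step, ms.
#' @return numeric vector of length `n_samples`, spikes/s.
#' @export
spike_density <- function(spike_times, t0, n_samples, sigma = 5, dt = 1) {
  stopifnot(sigma > 0, n_samples > 0)
  y <- numeric(n_samples)
  if (length(spike_times) == 0) return(y)
  grid <- t0 + (seq_len(n_samples) - 1) * dt
  half <- ceiling(5 * sigma / dt)
  for (s in spike_times) {
    i0 <- max(1L, floor((s - t0) / dt) - half)
    i1 <- min(n_samples, ceiling((s - t0) / dt) + half)
    if (i1 < 1 || i0 > n_samples) next
    idx <- i0:i1
    y[idx] <- y[idx] + stats::dnorm(grid[idx], mean = s, sd = sigma)
  }
  y * 1000
}

#' Trial-aligned spike density
#'
#' @param spike_times spike times, ms from trial start.
#' @param align_time alignment event time, ms.
#' @param window half-open window around the alignment event, ms.
#' @param sigma kernel SD, ms.
#' @return list with `t` (ms relative to the event, 1 ms grid) and `y`
#'   (spikes/s).
#' @export
aligned_density <- function(spike_times, align_time, window = c(-250, 250),
                            sigma = 5) {
  rel <- spike_times - align_time
  keep <- rel >= window[1] - 6 * sigma & rel < window[2] + 6 * sigma
  n <- as.integer(window[2] - window[1])
  list(t = window[1] + seq_len(n) - 1,
       y = spike_density(rel[keep], t0 = window[1], n_samples = n,
                         sigma = sigma))
}

#' Firing rate in an aligned half-open epoch
#'
#' @param spike_times spike times, ms from trial start.
#' @param window `c(lo, hi)` ms relative to the alignment event.
#' @param align_time alignment event time, ms (must be finite).
#' @return spikes/s.
#' @export
epoch_rate <- function(spike_times, window, align_time) {
  if (length(align_time) != 1 || !is.finite(align_time)) {
    stop("alignment event time is missing or non-finite")
  }
  window_rate(spike_times - align_time, window[1], window[2])
}

#' Divide activity by baseline rate
#'
#' Baseline division with a floor (default 1 spike/s) so near-silent baselines
#' cannot blow up the normalized values. Scale-invariant above the floor:
#' multiplying every rate of a neuron by c > 0 leaves the result unchanged.
#'
#' @param values rates, spikes/s.
#' @param baseline_rate the neuron's baseline rate, spikes/s.
#' @param floor minimum divisor, spikes/s.
#' @return dimensionless normalized activity.
#' @export
normalize_by_baseline <- function(values, baseline_rate, floor = 1) {
  values / max(baseline_rate, floor)
}

#' Pointwise population average with a 95% confidence interval
#'
#' Normal-approximation CI: mean +- 1.96 SEM at every time point. Traces of
#' unequal length are cropped to the common support.
#'
#' @param traces matrix (rows = traces) or list of numeric vectors.
#' @return list with `mean`, `lower`, `upper`, `sem`, `n`.
#' @export
population_average <- function(traces) {
  if (is.list(traces)) {
    len <- min(vapply(traces, length, 1L))
    traces <- do.call(rbind, lapply(traces, function(z) z[seq_len(len)]))
  }
  stopifnot(is.matrix(traces), nrow(traces) >= 2)
  m <- colMeans(traces)
  sem <- apply(traces, 2, stats::sd) / sqrt(nrow(traces))
  list(mean = m, lower = m - 1.96 * sem, upper = m + 1.96 * sem,
       sem = sem, n = nrow(traces))
}

# --- per-session activity helpers -----------------------------------------

.align_times <- function(trials_df, align) {
  switch(align,
         saccade_onset = trials_df$onset,
         saccade_end = trials_df$offset,
         fixation_onset = trials_df$fixation_onset,
         fp_offset = trials_df$fp_offset,
         stop("unknown alignment: ", align))
}

#' Per-trial epoch rates for one neuron
#'
#' @param session an `scs_session`.
#' @param neuron_id neuron id.
#' @param trials_df rows of the [detect_saccades()] table to evaluate.
#' @param window half-open window, ms relative to `align`.
#' @param align "saccade_onset", "saccade_end" or "fixation_onset".
#' @return numeric vector, one rate (spikes/s) per row of `trials_df`.
#' @export
trial_epoch_activity <- function(session, neuron_id, trials_df, window,
                                 align = "saccade_end") {
  at <- .align_times(trials_df, align)
  vapply(seq_len(nrow(trials_df)), function(k) {
    st <- session$trials[[trials_df$trial_id[k]]]$spikes[[neuron_id]]
    epoch_rate(st, window, at[k])
  }, numeric(1))
}

#' Mean baseline rate of a neuron
#'
#' Rate in the [100, 500) ms window after fixation onset, averaged across the
#' supplied trials.
#'
#' @inheritParams trial_epoch_activity
#' @return spikes/s.
#' @export
neuron_baseline_rate <- function(session, neuron_id, trials_df) {
  ep <- epoch_windows()$baseline_norm
  mean(trial_epoch_activity(session, neuron_id, trials_df, ep$window,
                            ep$align))
}

#' Trial-averaged aligned density matrix for one neuron
#'
#' @inheritParams trial_epoch_activity
#' @param window window around the alignment event, ms.
#' @param sigma kernel SD, ms.
#' @return list with `t` (relative ms), `mat` (trials x time matrix) and
#'   `mean` (trial-averaged density).
#' @export
neuron_aligned_density <- function(session, neuron_id, trials_df,
                                   align = "saccade_end",
                                   window = c(-250, 250), sigma = 5) {
  at <- .align_times(trials_df, align)
  rows <- lapply(seq_len(nrow(trials_df)), function(k) {
    st <- session$trials[[trials_df$trial_id[k]]]$spikes[[neuron_id]]
    aligned_density(st, at[k], window, sigma)$y
  })
  mat <- do.call(rbind, rows)
  list(t = window[1] + seq_len(ncol(mat)) - 1, mat = mat,
       mean = colMeans(mat))
}
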