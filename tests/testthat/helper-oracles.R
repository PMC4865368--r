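# Independent brute-force oracles. These deliberately re-state the detection
# definitions as naive sample-by-sample loops, sharing no code with the
# package implementations beyond the speed trace itself.

oracle_primary <- function(trace, fp_offset, speed,
                           search = 600, thr = 30, frac = 0.1) {
  t <- trace$t0 + (seq_along(trace$x) - 1) * trace$dt
  n <- length(t)
  onset_i <- NA
  for (i in seq_len(n)) {
    if (t[i] > fp_offset && t[i] < fp_offset + search && speed[i] > thr) {
      onset_i <- i
      break
    }
  }
  if (is.na(onset_i)) return(NULL)
  seg_end <- n
  for (i in onset_i:n) {
    if (speed[i] < thr) { seg_end <- i - 1; break }
  }
  peak_i <- onset_i
  for (i in onset_i:seg_end) if (speed[i] > speed[peak_i]) peak_i <- i
  offset_i <- NA
  if (peak_i < n) {
    for (i in (peak_i + 1):n) {
      if (speed[i] < frac * speed[peak_i]) { offset_i <- i; break }
    }
  }
  if (is.na(offset_i) || t[offset_i] + 20 > t[n]) return(NULL)
  list(onset = t[onset_i], offset = t[offset_i])
}

oracle_secondary <- function(trace, primary_offset, speed,
                             thr = 8, frac = 0.1, min_dur = 5,
                             min_amp = 0.2, min_gap = 100) {
  t <- trace$t0 + (seq_along(trace$x) - 1) * trace$dt
  n <- length(t)
  out <- list()
  i <- 1
  while (i <= n && t[i] < primary_offset + min_gap) i <- i + 1
  while (i <= n) {
    while (i <= n && speed[i] <= thr) i <- i + 1
    if (i > n) break
    onset_i <- i
    seg_end <- n
    for (k in onset_i:n) if (speed[k] < thr) { seg_end <- k - 1; break }
    peak_i <- onset_i
    for (k in onset_i:seg_end) if (speed[k] > speed[peak_i]) peak_i <- k
    offset_i <- NA
    if (peak_i < n) {
      for (k in (peak_i + 1):n) {
        if (speed[k] < frac * speed[peak_i]) { offset_i <- k; break }
      }
    }
    if (is.na(offset_i)) break
    dur <- t[offset_i] - t[onset_i]
    amp <- sqrt((trace$x[offset_i] - trace$x[onset_i])^2 +
                  (trace$y[offset_i] - trace$y[onset_i])^2)
    if (t[offset_i] + 20 <= t[n] && dur > min_dur && amp > min_amp) {
      out[[length(out) + 1]] <- list(onset = t[onset_i], offset = t[offset_i])
    }
    i <- offset_i + 1
  }
  out
}

# Time-rescaling sampler for an inhomogeneous Poisson process: integrate the
# rate on a fine grid and invert unit-rate exponential waiting times.
oracle_rescaling_sampler <- function(rate_fn, duration, dt = 0.5) {
  grid <- seq(0, duration, by = dt)
  rate <- rate_fn(grid)
  cum <- cumsum(rate) * dt / 1000 # integrated rate (expected counts)
  spikes <- numeric(0)
  target <- stats::rexp(1)
  repeat {
    if (target > cum[length(cum)]) break
    idx <- which(cum >= target)[1]
    spikes <- c(spikes, grid[idx])
    target <- target + stats::rexp(1)
  }
  spikes
}
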