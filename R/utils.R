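#' @keywords internal
"_PACKAGE"

# Times are milliseconds from trial start; analysis windows are half-open
# [a, b) so a spike on a boundary is counted exactly once.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Spike count in a half-open window
#' @noRd
count_in_window <- function(times, lo, hi) {
  sum(times >= lo & times < hi)
}

#' Firing rate (spikes/s) in a half-open window given in ms
#' @noRd
window_rate <- function(times, lo, hi) {
  1000 * count_in_window(times, lo, hi) / (hi - lo)
}

# Deterministic substream seeds. A session seed is mixed with small integer
# ids (stage, neuron index, trial index) through an LCG-style hash so that
# trial k's behaviour does not depend on how many neurons exist, and neuron
# j's spikes do not depend on other neurons. Result is a valid 32-bit seed.
mix_seed <- function(seed, ...) {
  ids <- c(...)
  h <- (abs(as.double(seed)) + 1) %% 2147483647
  for (k in ids) {
    h <- (h * 48271 + (as.double(k) + 1) * 16807 + 11) %% 2147483647
  }
  as.integer(h %% 2147483399) + 1L
}

#' Signed horizontal position mapped into motor coordinates
#'
#' Pools leftward and rightward trials by sign-flipping leftward positions so
#' the saccade target always maps to +eccentricity.
#'
#' @param x signed horizontal position, degrees (rightward positive).
#' @param direction character vector, "left" or "right".
#' @return position in motor coordinates, degrees.
#' @export
motor_position <- function(x, direction) {
  ifelse(direction == "left", -x, x)
}

# p value or NA from a test that may fail on degenerate input
safe_p <- function(expr) {
  out <- tryCatch(suppressWarnings(expr), error = function(e) NULL)
  if (is.null(out)) NA_real_ else unname(out$p.value)
}

safe_stat <- function(expr) {
  out <- tryCatch(suppressWarnings(expr), error = function(e) NULL)
  if (is.null(out)) NA_real_ else unname(out$statistic)
}
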