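# Relating post-subtraction activity to corrective (secondary) saccades.
#
# The same end-position bin edges as the comparator analysis are reused so
# that activity and probability are computed on identical trial partitions.
# Trials must pass the primary-saccade filters; secondary saccades of any
# direction count.

#' Secondary-saccade probability per end-position bin
#'
#' @param trials_df [detect_saccades()] rows (included trials only are used).
#' @param edges end-position bin edges, motor coordinates, degrees.
#' @param target target eccentricity (split point for the piecewise fits).
#' @return object of class `secondary_stats`: data frame with per-bin trial
#'   counts with/without a secondary saccade and the empirical probability,
#'   plus piecewise (undershoot/overshoot) linear fits of probability vs
#'   position in the `prob_fit` attribute.
#' @export
secondary_probability_by_bin <- function(trials_df, edges, target = NULL) {
  ok <- trials_df[trials_df$passed, ]
  k <- length(edges) - 1
  idx <- clamp(findInterval(ok$end_motor, edges, rightmost.closed = TRUE), 1, k)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  rows <- lapply(seq_len(k), function(b) {
    sel <- idx == b
    n_with <- sum(ok$has_secondary[sel])
    n_without <- sum(sel) - n_with
    data.frame(bin = b, lo = lo[b], hi = hi[b], center = (lo[b] + hi[b]) / 2,
               n = sum(sel), n_with = n_with, n_without = n_without,
               probability = if (sum(sel) == 0) NA_real_ else n_with / sum(sel))
  })
  out <- do.call(rbind, rows)
  prob_fit <- NULL
  if (!is.null(target)) {
    bn <- structure(
      data.frame(lo = out$lo, hi = out$hi, center = out$center, n = out$n,
                 mean = out$probability, sem = NA_real_),
      edges = edges, class = c("binned_activity", "data.frame"))
    prob_fit <- piecewise_linear_fit(bn, split_at = target)
  }
  structure(out, prob_fit = prob_fit, edges = edges,
            class = c("secondary_stats", "data.frame"))
}

#' Correlation between post-subtraction activity and secondary probability
#'
#' Pearson correlation across end-position bins between the per-bin mean
#' post-subtraction activity and the per-bin secondary-saccade probability.
#'
#' @param probability per-bin secondary probabilities.
#' @param activity per-bin mean post-subtraction activity (same bins).
#' @return list with `r`, `p` and `n_bins`; `r` is NA (with a reason) when a
#'   vector is constant.
#' @export
correlate_activity_with_probability <- function(probability, activity) {
  keep <- is.finite(probability) & is.finite(activity)
  probability <- probability[keep]
  activity <- activity[keep]
  if (length(probability) < 4) stop("need at least 4 usable bins")
  if (stats::sd(probability) == 0 || stats::sd(activity) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_bins = length(probability),
                reason = "constant vector"))
  }
  ct <- stats::cor.test(activity, probability)
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = length(probability))
}

#' Per-bin comparison of activity with vs without a secondary saccade
#'
#' Within each end-position bin, rank-sum test of the per-trial
#' post-subtraction activity between trials with and without a secondary
#' saccade. Bins with an empty subgroup are skipped.
#'
#' @param trial_activity data frame with `x` (end position, motor
#'   coordinates), `activity` (per-trial post-subtraction activity, pooled
#'   over neurons) and `has_secondary`.
#' @param edges bin edges, motor coordinates.
#' @param min_per_group minimum trials per subgroup for a bin to be testable.
#' @return data frame with per-bin means of both subgroups, their difference,
#'   subgroup sizes and the rank-sum p value (NA for untestable bins).
#' @export
compare_with_without_secondary <- function(trial_activity, edges,
                                           min_per_group = 2) {
  k <- length(edges) - 1
  idx <- clamp(findInterval(trial_activity$x, edges,
                            rightmost.closed = TRUE), 1, k)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  rows <- lapply(seq_len(k), function(b) {
    sel <- idx == b
    a_with <- trial_activity$activity[sel & trial_activity$has_secondary]
    a_without <- trial_activity$activity[sel & !trial_activity$has_secondary]
    testable <- length(a_with) >= min_per_group &&
      length(a_without) >= min_per_group
    p <- if (testable) {
      suppressWarnings(stats::wilcox.test(a_with, a_without,
                                          exact = FALSE)$p.value)
    } else NA_real_
    data.frame(bin = b, center = (lo[b] + hi[b]) / 2,
               n_with = length(a_with), n_without = length(a_without),
               mean_with = if (length(a_with)) mean(a_with) else NA_real_,
               mean_without = if (length(a_without)) mean(a_without) else NA_real_,
               difference = if (length(a_with) && length(a_without)) {
                 mean(a_with) - mean(a_without)
               } else NA_real_,
               p = p, testable = testable)
  })
  do.call(rbind, rows)
}
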