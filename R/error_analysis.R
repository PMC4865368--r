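# The comparator analysis: end-position binning, single-trial correlations,
# reference-subtraction normalization, piecewise regression, the subtraction
# model and the sliding-window error correlation.
#
# All end positions here are horizontal, in motor coordinates (the preferred
# target maps to +eccentricity), and activities are baseline-divided
# (normalize_by_baseline) before any reference subtraction.

#' Saccadic error along the horizontal meridian
#'
#' @param end_position_h horizontal end position, motor coordinates, degrees.
#' @param target target eccentricity, degrees.
#' @return absolute error, degrees.
#' @export
saccadic_error <- function(end_position_h, target) {
  abs(end_position_h - target)
}

#' Bin trials by horizontal end position
#'
#' Equal-width bins spanning mean +- `span_sd` SD of the positions (edge bins
#' absorb outliers); bins with fewer than `min_trials` entries are merged
#' with their nearest neighbour unless a fixed `edges` grid is supplied, in
#' which case under-filled bins are kept (with NA mean) so that several
#' activities can share one grid.
#'
#' @param positions horizontal end positions, motor coordinates, degrees.
#' @param values per-trial activity (any epoch, any normalization).
#' @param n_bins requested bin count (16 for PPS pools, 6 for LPS pools).
#' @param min_trials minimum trials per bin before merging.
#' @param span_sd half-width of the binned range, in SDs of `positions`.
#' @param edges optional fixed bin edges (overrides `n_bins`, no merging).
#' @return object of class `binned_activity`: data frame with `lo`, `hi`,
#'   `center` (geometric bin center), `x_mean` (mean position of the trials
#'   in the bin, used by the regression helpers), `n`, `mean`, `sem` and an
#'   `edges` attribute.
#' @export
bin_by_end_position <- function(positions, values, n_bins = 16,
                                min_trials = 5, span_sd = 3, edges = NULL) {
  stopifnot(length(positions) == length(values))
  merge_small <- is.null(edges)
  if (is.null(edges)) {
    m <- mean(positions)
    s <- stats::sd(positions)
    if (is.na(s) || s == 0) {
      edges <- c(m - 0.5, m + 0.5) # degenerate: all positions identical
    } else {
      edges <- seq(m - span_sd * s, m + span_sd * s, length.out = n_bins + 1)
    }
  }
  k <- length(edges) - 1
  idx <- findInterval(positions, edges, rightmost.closed = TRUE)
  idx <- clamp(idx, 1, k) # outliers into the edge bins
  bins <- lapply(seq_len(k), function(b) which(idx == b))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  if (merge_small) {
    repeat {
      counts <- lengths(bins)
      if (length(bins) < 2 || all(counts >= min_trials)) break
      b <- which.min(counts)
      nb <- if (b == 1) 2 else if (b == length(bins)) b - 1 else {
        if (counts[b - 1] <= counts[b + 1]) b - 1 else b + 1
      }
      lohi <- sort(c(b, nb))
      bins[[lohi[1]]] <- c(bins[[lohi[1]]], bins[[lohi[2]]])
      bins[[lohi[2]]] <- NULL
      hi[lohi[1]] <- hi[lohi[2]]
      lo <- lo[-lohi[2]]
      hi <- hi[-lohi[2]]
    }
  }
  if (length(positions) == 0) stop("no positions to bin")
  df <- data.frame(
    lo = lo, hi = hi, center = (lo + hi) / 2,
    # mean position of the trials actually in the bin: regression and
    # prediction use this, since in skewed tail bins the geometric center
    # can sit far from where the trials are (aggregation bias)
    x_mean = vapply(bins, function(i) {
      if (length(i) == 0) NA_real_ else mean(positions[i])
    }, numeric(1)),
    n = lengths(bins),
    mean = vapply(bins, function(i) {
      if (length(i) == 0) NA_real_ else mean(values[i])
    }, numeric(1)),
    sem = vapply(bins, function(i) {
      if (length(i) < 2) NA_real_ else stats::sd(values[i]) / sqrt(length(i))
    }, numeric(1)))
  structure(df, edges = c(lo, hi[length(hi)]), class = c("binned_activity",
                                                         "data.frame"))
}

#' Single-trial activity vs position correlation, per neuron and population
#'
#' Pearson correlation of per-trial activity against a per-trial covariate
#' for each neuron, followed by a population-level one-sample t-test of the
#' per-neuron r values against zero. Neurons with fewer than `min_trials`
#' usable trials or zero-variance activity are excluded (and listed).
#'
#' @param df long data frame with columns `neuron_id`, `activity`, `x`.
#' @param min_trials minimum trials per neuron (default 30).
#' @return object of class `correlation_result`: list with `per_neuron`
#'   (neuron_id, n, r, p), `mean_r`, `population_p`, `n_neurons`, `excluded`.
#' @export
single_trial_correlation <- function(df, min_trials = 30) {
  stopifnot(all(c("neuron_id", "activity", "x") %in% names(df)))
  excluded <- character(0)
  rows <- lapply(split(df, df$neuron_id), function(sub) {
    if (nrow(sub) < min_trials || stats::sd(sub$activity) == 0 ||
        stats::sd(sub$x) == 0) {
      excluded <<- c(excluded, sub$neuron_id[1])
      return(NULL)
    }
    ct <- stats::cor.test(sub$activity, sub$x)
    data.frame(neuron_id = sub$neuron_id[1], n = nrow(sub),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per) || nrow(per) < 2) {
    stop("fewer than 2 neurons usable for the population correlation test")
  }
  pop_p <- if (stats::sd(per$r) == 0) NA_real_ else {
    stats::t.test(per$r, mu = 0)$p.value
  }
  structure(list(per_neuron = per, mean_r = mean(per$r),
                 population_p = pop_p, n_neurons = nrow(per),
                 excluded = excluded),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d neurons, mean r = %.4f (p = %.3g)\n",
              x$n_neurons, x$mean_r, x$population_p))
  invisible(x)
}

#' Reference-subtract a binned activity
#'
#' Subtracts the mean activity of the bin containing the target (the
#' reference condition: saccades ending at the target) from every bin, so the
#' reference bin maps to 0 by construction. Idempotent.
#'
#' @param binned a `binned_activity`.
#' @param target target eccentricity, degrees.
#' @return the shifted `binned_activity`.
#' @export
reference_normalize <- function(binned, target) {
  hit <- which(binned$lo <= target & target < binned$hi)
  if (length(hit) == 0) {
    hit <- which(binned$lo <= target & target <= binned$hi) # top edge
  }
  if (length(hit) == 0 || is.na(binned$mean[hit[1]])) {
    stop("no populated bin covers the target position")
  }
  binned$mean <- binned$mean - binned$mean[hit[1]]
  binned
}

# weighted least squares of bin means on bin positions (mean position of the
# trials in the bin where available, geometric center otherwise)
.bin_x <- function(binned) {
  x <- binned$x_mean %||% binned$center
  ifelse(is.na(x), binned$center, x)
}

.wls <- function(binned, sel) {
  sub <- binned[sel & !is.na(binned$mean) & binned$n > 0, ]
  if (nrow(sub) < 2) return(NULL)
  sub$x <- .bin_x(sub)
  fit <- stats::lm(mean ~ x, data = sub, weights = sub$n)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]), n_bins = nrow(sub))
}

#' Piecewise (hypometric/hypermetric) linear fit of binned activity
#'
#' Separate weighted least-squares lines on bin centers below and above the
#' split (default: the target eccentricity, so the two sides are
#' undershooting and overshooting saccades). A side with fewer than 2 usable
#' bins is reported absent (NULL).
#'
#' @param binned a `binned_activity`.
#' @param split_at split position, degrees.
#' @return list with `lower` and `upper` fits (`intercept`, `slope`,
#'   `n_bins`).
#' @export
piecewise_linear_fit <- function(binned, split_at) {
  x <- .bin_x(binned)
  list(lower = .wls(binned, x <= split_at),
       upper = .wls(binned, x >= split_at))
}

#' Subtraction model of the post-subtraction error signal
#'
#' Linear fits of the normalized, reference-subtracted LPS post-saccadic and
#' PPS perisaccadic activities against end position predict the error signal
#' as their absolute difference; the prediction is compared with the observed
#' post-subtraction PPS activity on the same bin grid via the RMS deviation
#' over populated bins.
#'
#' @param pps_peri_binned,lps_post_binned,pps_postsub_binned
#'   reference-normalized `binned_activity` objects on a common bin grid.
#' @return object of class `subtraction_model_result`: the two linear fits,
#'   the piecewise fit of the observed post-subtraction activity, the
#'   predicted |LPS - PPS| curve on bin centers, and `agreement_rms`.
#' @export
subtraction_model <- function(pps_peri_binned, lps_post_binned,
                              pps_postsub_binned) {
  same_grid <- function(a, b) {
    ea <- attr(a, "edges"); eb <- attr(b, "edges")
    length(ea) == length(eb) && max(abs(ea - eb)) < 1e-9
  }
  if (!same_grid(pps_peri_binned, pps_postsub_binned) ||
      !same_grid(lps_post_binned, pps_postsub_binned)) {
    stop("binned activities are not on a common bin grid")
  }
  fit_pps <- .wls(pps_peri_binned, rep(TRUE, nrow(pps_peri_binned)))
  fit_lps <- .wls(lps_post_binned, rep(TRUE, nrow(lps_post_binned)))
  if (is.null(fit_pps) || is.null(fit_lps)) {
    stop("too few populated bins for the linear fits")
  }
  centers <- .bin_x(pps_postsub_binned)
  predicted <- abs((fit_lps$intercept + fit_lps$slope * centers) -
                     (fit_pps$intercept + fit_pps$slope * centers))
  observed <- pps_postsub_binned$mean
  usable <- !is.na(observed) & pps_postsub_binned$n > 0
  # vertex of the predicted V locates the piecewise split for the observed fit
  split_at <- if (fit_lps$slope != fit_pps$slope) {
    (fit_pps$intercept - fit_lps$intercept) / (fit_lps$slope - fit_pps$slope)
  } else {
    mean(centers)
  }
  structure(list(
    pps_peri_fit = fit_pps, lps_post_fit = fit_lps,
    observed_fit = piecewise_linear_fit(pps_postsub_binned, split_at),
    centers = centers, predicted = predicted, observed = observed,
    agreement_rms = sqrt(mean((predicted[usable] - observed[usable])^2))),
    class = "subtraction_model_result")
}

# Long-format normalized activity table used by the population analyses:
# one row per (neuron, preferred included trial).
#' Normalized per-trial epoch activity for a set of neurons
#'
#' For each neuron: keep its preferred-direction included trials, compute the
#' epoch rate aligned at the detected saccade, divide by the neuron's
#' baseline rate, and optionally subtract the neuron's mean activity over the
#' reference trials (trials whose end position falls in the bin containing
#' the target).
#'
#' @param session an `scs_session`.
#' @param trials_df the [detect_saccades()] table.
#' @param neurons data frame with `neuron_id` and `preferred_direction`.
#' @param window epoch window, ms relative to `align`.
#' @param align alignment event.
#' @param reference_edges optional bin edges (motor coordinates): when given,
#'   each neuron's mean activity over trials in the bin containing
#'   `target` is subtracted.
#' @param target target eccentricity, degrees (needed for the reference).
#' @return data frame with `neuron_id`, `trial_id`, `x` (end position, motor
#'   coordinates), `error`, `amplitude`, `has_secondary`, `activity`.
#' @export
activity_table <- function(session, trials_df, neurons, window,
                           align = "saccade_end", reference_edges = NULL,
                           target = NULL) {
  rows <- lapply(seq_len(nrow(neurons)), function(j) {
    nid <- neurons$neuron_id[j]
    pref <- neurons$preferred_direction[j]
    sub <- trials_df[trials_df$passed & trials_df$direction == pref, ]
    if (nrow(sub) == 0) return(NULL)
    act <- trial_epoch_activity(session, nid, sub, window, align)
    act <- normalize_by_baseline(act, neuron_baseline_rate(session, nid, sub))
    if (!is.null(reference_edges)) {
      stopifnot(!is.null(target))
      b <- findInterval(target, reference_edges, rightmost.closed = TRUE)
      in_ref <- findInterval(sub$end_motor, reference_edges,
                             rightmost.closed = TRUE) == b
      if (!any(in_ref)) {
        stop("neuron ", nid, ": no trials in the reference bin")
      }
      act <- act - mean(act[in_ref])
    }
    data.frame(neuron_id = nid, trial_id = sub$trial_id,
               x = sub$end_motor, error = sub$error,
               amplitude = sub$amplitude,
               has_secondary = sub$has_secondary,
               activity = act, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Sliding-window correlation between activity and saccadic error
#'
#' A 100 ms window slid in 10 ms steps over [0, 450] ms after saccade end:
#' in each window, the per-neuron Pearson correlation between the window
#' rate and the absolute saccadic error is computed over the neuron's
#' preferred included trials, then the per-neuron r values are tested
#' against zero (one-sample t-test). Windows are stamped by their midpoint.
#'
#' @param session an `scs_session`.
#' @param trials_df the [detect_saccades()] table.
#' @param neurons data frame with `neuron_id`, `preferred_direction`.
#' @param window window length, ms.
#' @param step step, ms.
#' @param span start range of the windows, ms after saccade end.
#' @param min_trials minimum trials per neuron.
#' @return data frame with `t_mid`, `mean_r`, `p`, `n_neurons`.
#' @export
sliding_window_error_correlation <- function(session, trials_df, neurons,
                                             window = 100, step = 10,
                                             span = c(0, 450),
                                             min_trials = 30) {
  starts <- seq(span[1], span[2] - window, by = step)
  # gather aligned spikes once per neuron
  per_neuron <- lapply(seq_len(nrow(neurons)), function(j) {
    nid <- neurons$neuron_id[j]
    pref <- neurons$preferred_direction[j]
    sub <- trials_df[trials_df$passed & trials_df$direction == pref, ]
    if (nrow(sub) < min_trials) return(NULL)
    spikes <- lapply(seq_len(nrow(sub)), function(k) {
      session$trials[[sub$trial_id[k]]]$spikes[[nid]] - sub$offset[k]
    })
    list(spikes = spikes, error = sub$error)
  })
  per_neuron <- per_neuron[!vapply(per_neuron, is.null, TRUE)]
  if (length(per_neuron) < 2) stop("too few neurons with enough trials")
  rows <- lapply(starts, function(s) {
    rs <- vapply(per_neuron, function(pn) {
      counts <- vapply(pn$spikes, function(st) {
        count_in_window(st, s, s + window)
      }, numeric(1))
      if (stats::sd(counts) == 0) return(NA_real_)
      stats::cor(counts, pn$error)
    }, numeric(1))
    rs <- rs[!is.na(rs)]
    tt <- stats::t.test(rs, mu = 0)
    data.frame(t_mid = s + window / 2, mean_r = mean(rs), p = tt$p.value,
               n_neurons = length(rs))
  })
  do.call(rbind, rows)
}
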