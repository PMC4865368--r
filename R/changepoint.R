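# Exponential-fit change-point estimation of firing-rate transitions.
#
# Decay of peri-saccadic activity: find the peak of the trial-averaged spike
# density with a 20 ms moving window (1 ms step); the end point is the
# minimum activity after the peak; a "fluctuation period" runs from the peak
# to the first point where activity drops below the peak by 2 STE or below
# 80% of the peak (whichever bound is crossed first); an exponential
# y = A1 * exp(x / A2) + A3 is fitted from every candidate start inside the
# fluctuation period to the end point, and the start with the minimum mean
# squared residual is the decay time. The rise estimator mirrors this around
# the trough preceding the peak. STE is the standard error of the
# across-trial mean density within the 20 ms peak (or trough) window.

#' Nonlinear least-squares exponential fit
#'
#' Fits `y = A1 * exp(x / A2) + A3` with x re-expressed relative to the first
#' sample. Initialisation: A3 = last value, A1 = first - last,
#' A2 = -(range of x)/3; up to 200 iterations. When `weights` are supplied
#' the fit minimises the weighted squared residuals and `residual` is their
#' (weighted) mean.
#'
#' @param x,y numeric vectors of equal length (>= 4 points).
#' @param weights optional non-negative weights, same length as `y`.
#' @return list with `A1`, `A2`, `A3` and `residual` (mean squared error), or
#'   `NULL` when the fit fails to converge.
#' @export
fit_exponential <- function(x, y, weights = NULL) {
  if (length(x) < 4) return(NULL)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  sw <- sqrt(w)
  x0 <- x - x[1]
  span <- max(x0[length(x0)], 1)
  start <- c(A1 = y[1] - y[length(y)],
             A2 = -span / 3,
             A3 = y[length(y)])
  if (abs(start[["A1"]]) < 1e-8) start[["A1"]] <- 1e-8
  model <- function(p) {
    # cap the exponent so a degenerate A2 cannot overflow
    p[1] * exp(pmin(pmax(x0 / p[2], -700), 700)) + p[3]
  }
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start,
      fn = function(p) sw * (y - model(p)),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par))) return(NULL)
  res <- sw * (y - model(fit$par))
  if (!all(is.finite(res))) return(NULL)
  list(A1 = unname(fit$par[["A1"]]), A2 = unname(fit$par[["A2"]]),
       A3 = unname(fit$par[["A3"]]), residual = mean(res^2))
}

# centred 20 ms moving mean (1 ms step), same length, NA at the edges
.moving_mean <- function(y, width = 20) {
  as.numeric(stats::filter(y, rep(1 / width, width), sides = 2))
}

.no_changepoint <- function(reason) {
  structure(list(ok = FALSE, reason = reason, time = NA_real_, fit = NULL,
                 fluctuation = c(NA_real_, NA_real_), end_time = NA_real_,
                 candidates_evaluated = 0L),
            class = "changepoint_fit")
}

.changepoint_result <- function(kind, time, fit, fluct, end_time, n_cand) {
  structure(list(ok = TRUE, kind = kind, time = time, fit = fit,
                 fluctuation = fluct, end_time = end_time,
                 candidates_evaluated = n_cand),
            class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  if (!x$ok) {
    cat("<changepoint_fit> no change point (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "<changepoint_fit> %s time = %.1f ms (fluctuation %.0f..%.0f ms, %d candidates, mse %.3g)\n",
      x$kind, x$time, x$fluctuation[1], x$fluctuation[2],
      x$candidates_evaluated, x$fit$residual))
  }
  invisible(x)
}

# STE of the across-trial mean density within a 20 ms window centred at idx
.window_ste <- function(mat, idx, width = 20) {
  if (is.null(mat) || nrow(mat) < 2) return(0)
  lo <- max(1, idx - width %/% 2)
  hi <- min(ncol(mat), idx + width %/% 2 - 1)
  per_trial <- rowMeans(mat[, lo:hi, drop = FALSE])
  stats::sd(per_trial) / sqrt(nrow(mat))
}

# Per-timepoint weights for the candidate scan: inverse variance of the
# trial-mean density (smoothed and floored). Without them the minimum-MSE
# rule favours late starts purely because Poisson variance scales with rate.
.scan_weights <- function(mat) {
  if (is.null(mat) || nrow(mat) < 2) return(NULL)
  v <- apply(mat, 2, stats::var) / nrow(mat)
  vs <- .moving_mean(v, 20)
  vs[is.na(vs)] <- v[is.na(vs)]
  vs <- pmax(vs, max(vs) * 1e-3, 1e-12)
  1 / vs
}

# Scan candidate starts, fitting each segment [s, end] and keeping the start
# of the minimum-MSE fit (the earliest start on exact ties, which is what a
# noiseless planted transition produces).
.best_start <- function(times, y, candidates, end_idx, weights = NULL) {
  fits <- vector("list", length(candidates))
  n_eval <- 0L
  for (k in seq_along(candidates)) {
    s <- candidates[k]
    if (end_idx - s + 1 < 8) next
    f <- fit_exponential(times[s:end_idx], y[s:end_idx],
                         if (is.null(weights)) NULL else weights[s:end_idx])
    if (is.null(f)) next # non-convergent candidate: skipped
    n_eval <- n_eval + 1L
    fits[[k]] <- list(idx = s, fit = f, n = end_idx - s + 1)
  }
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (length(fits) == 0) return(NULL)
  mses <- vapply(fits, function(f) f$fit$residual, numeric(1))
  best <- fits[[which.min(mses)]]
  best$n_eval <- n_eval
  best
}

#' Estimate the decay time of peri-saccadic activity
#'
#' @param density either the list returned by [neuron_aligned_density()]
#'   (per-trial matrix plus mean) or a plain numeric mean-density vector.
#' @param times time grid in ms relative to the alignment event; taken from
#'   `density$t` when omitted.
#' @param ste standard error of the mean density in the peak window; computed
#'   from the per-trial matrix when available, else 0.
#' @param peak_window width of the moving window used to locate the peak, ms.
#' @return a `changepoint_fit`; `ok = FALSE` with a reason when the trace has
#'   no decaying transition.
#' @export
estimate_decay_time <- function(density, times = NULL, ste = NULL,
                                peak_window = 20) {
  mat <- NULL
  if (is.list(density) && !is.null(density$mean)) {
    mat <- density$mat
    if (is.null(times)) times <- density$t
    y <- density$mean
  } else {
    y <- as.numeric(density)
  }
  if (is.null(times)) times <- seq_along(y) - 1
  sm <- .moving_mean(y, peak_window)
  valid <- which(!is.na(sm))
  if (length(valid) < 2 * peak_window) return(.no_changepoint("trace too short"))
  peak_idx <- valid[which.max(sm[valid])]
  peak_val <- sm[peak_idx]
  if (is.null(ste)) ste <- .window_ste(mat, peak_idx, peak_window)
  after <- which(seq_along(y) > peak_idx)
  if (length(after) < 8) return(.no_changepoint("peak at trace end"))
  end_idx <- after[which.min(y[after])]
  if (y[end_idx] >= peak_val - 1e-12) {
    return(.no_changepoint("no decay after peak"))
  }
  # The fluctuation period ends at the point after which activity *stays*
  # below the bound (peak - 2 STE, or 80% of peak) all the way to the end
  # point: a transient noise dip on the plateau must not terminate it, or the
  # true transition would fall outside the candidate set. Evaluated on the
  # raw density; the moving mean would push the boundary early.
  thr <- max(peak_val - 2 * ste, 0.8 * peak_val)
  upto <- after[after <= end_idx]
  running_max <- rev(cummax(rev(y[upto])))
  cross <- upto[running_max < thr]
  if (length(cross) == 0) return(.no_changepoint("activity never leaves the peak"))
  fluct <- peak_idx:cross[1]
  best <- .best_start(times, y, fluct, end_idx, .scan_weights(mat))
  if (is.null(best)) return(.no_changepoint("no exponential fit converged"))
  .changepoint_result("decay", times[best$idx],
                      c(best$fit, start_time = times[best$idx]),
                      times[range(fluct)], times[end_idx], best$n_eval)
}

#' Estimate the rise time of post-saccadic activity
#'
#' Mirror of [estimate_decay_time()]: locate the peak, take the lowest point
#' before it, define the fluctuation period from that trough to the last
#' point still below the trough + 2 STE or below baseline + 2 STE, and fit
#' exponentials from every candidate start to the peak.
#'
#' @inheritParams estimate_decay_time
#' @param baseline baseline activity used for the trough bound; default is
#'   the mean of the first 100 ms of the trace.
#' @return a `changepoint_fit`.
#' @export
estimate_rise_time <- function(density, times = NULL, ste = NULL,
                               baseline = NULL, peak_window = 20) {
  mat <- NULL
  if (is.list(density) && !is.null(density$mean)) {
    mat <- density$mat
    if (is.null(times)) times <- density$t
    y <- density$mean
  } else {
    y <- as.numeric(density)
  }
  if (is.null(times)) times <- seq_along(y) - 1
  sm <- .moving_mean(y, peak_window)
  valid <- which(!is.na(sm))
  if (length(valid) < 2 * peak_window) return(.no_changepoint("trace too short"))
  peak_idx <- valid[which.max(sm[valid])]
  peak_val <- sm[peak_idx]
  before <- valid[valid < peak_idx]
  if (length(before) < 8) return(.no_changepoint("peak at trace start"))
  i_tr <- before[which.min(sm[before])]
  if (is.null(ste)) {
    # variability at baseline level: the trough window itself is a low-count
    # extreme whose own SEM understates the noise band around baseline
    if (!is.null(mat) && nrow(mat) >= 2) {
      base_seg <- seq_len(min(150, ncol(mat)))
      sem_t <- apply(mat[, base_seg, drop = FALSE], 2, stats::sd) /
        sqrt(nrow(mat))
      ste <- mean(sem_t)
    } else {
      ste <- 0
    }
  }
  # last sample statistically at the trough level, so a noisy early argmin
  # cannot exclude the true rise from the candidate range
  trough_idx <- max(before[y[before] <= sm[i_tr] + ste])
  trough_val <- sm[i_tr]
  if (peak_val <= trough_val + 1e-12) {
    return(.no_changepoint("no rise before peak"))
  }
  if (is.null(baseline)) {
    baseline <- mean(y[seq_len(min(100, length(y)))])
  }
  thr <- max(trough_val + 2 * ste, baseline + 2 * ste)
  seg <- trough_idx:peak_idx
  below <- seg[y[seg] <= thr + 1e-12]
  if (length(below) == 0) return(.no_changepoint("no quiescent period before rise"))
  fluct <- trough_idx:below[length(below)]
  best <- .best_start(times, y, fluct, peak_idx, .scan_weights(mat))
  if (is.null(best)) return(.no_changepoint("no exponential fit converged"))
  .changepoint_result("rise", times[best$idx],
                      c(best$fit, start_time = times[best$idx]),
                      times[range(fluct)], times[peak_idx], best$n_eval)
}

#' Middle point of an activity change
#'
#' Time at which a population trace crosses the midpoint between its
#' pre-change plateau and its post-change extreme (peak-to-trough for a
#' decay, trough-to-peak for a rise), with linear interpolation between
#' samples.
#'
#' @param y population mean trace.
#' @param times time grid, ms.
#' @param kind "decay", "rise", or "auto" (decay when the maximum precedes
#'   the minimum).
#' @return crossing time, ms.
#' @export
middle_point_of_change <- function(y, times = NULL,
                                   kind = c("auto", "decay", "rise")) {
  kind <- match.arg(kind)
  if (is.null(times)) times <- seq_along(y) - 1
  i_max <- which.max(y)
  i_min <- which.min(y)
  if (kind == "auto") kind <- if (i_max < i_min) "decay" else "rise"
  if (kind == "decay") {
    from <- i_max
    seg <- y[i_max:length(y)]
    extreme <- min(seg)
    mid <- (y[i_max] + extreme) / 2
    rel <- which(seg <= mid)
    if (length(rel) == 0 || y[i_max] == extreme) stop("no midpoint crossing")
    j <- from + rel[1] - 1
  } else {
    i_min <- which.min(y[1:i_max])
    from <- i_min
    seg <- y[i_min:i_max]
    mid <- (y[i_min] + y[i_max]) / 2
    rel <- which(seg >= mid)
    if (length(rel) == 0 || y[i_min] == y[i_max]) stop("no midpoint crossing")
    j <- from + rel[1] - 1
  }
  if (j == from) return(times[j])
  # linear interpolation between the bracketing samples
  y0 <- y[j - 1]; y1 <- y[j]
  frac <- if (y1 == y0) 0 else (mid - y0) / (y1 - y0)
  times[j - 1] + frac * (times[j] - times[j - 1])
}
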