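# Minimal base-graphics displays for the two objects people look at most.

#' Plot a population average trace with its confidence band
#'
#' @param pop output of [population_average()].
#' @param times time grid (ms).
#' @param ... passed to [plot()].
#' @export
plot_population_average <- function(pop, times = NULL, ...) {
  if (is.null(times)) times <- seq_along(pop$mean) - 1
  graphics::plot(times, pop$mean, type = "n",
                 ylim = range(pop$lower, pop$upper),
                 xlab = "time (ms)", ylab = "rate (spikes/s)", ...)
  graphics::polygon(c(times, rev(times)), c(pop$lower, rev(pop$upper)),
                    col = grDevices::adjustcolor("grey60", 0.5), border = NA)
  graphics::lines(times, pop$mean, lwd = 2)
  invisible(pop)
}

#' Plot binned activity against end position
#'
#' @param binned a `binned_activity`.
#' @param ... passed to [plot()].
#' @export
plot_binned_activity <- function(binned, ...) {
  ok <- !is.na(binned$mean)
  graphics::plot(binned$center[ok], binned$mean[ok], pch = 16,
                 xlab = "horizontal end position (deg)",
                 ylab = "normalized activity", ...)
  sem <- binned$sem[ok]
  has_sem <- is.finite(sem)
  graphics::arrows(binned$center[ok][has_sem],
                   (binned$mean[ok] - sem)[has_sem],
                   binned$center[ok][has_sem],
                   (binned$mean[ok] + sem)[has_sem],
                   angle = 90, code = 3, length = 0.03)
  invisible(binned)
}
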