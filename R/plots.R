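#' Plot a control chart
#'
#' Statistic versus time with the control limit shaded and alarmed minutes
#' marked along the top (spark-chart style).
#'
#' @param x a [control_chart()].
#' @param log_y plot the statistic on a log scale (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.control_chart <- function(x, log_y = TRUE, ...) {
  ok <- !is.na(x$statistic)
  ylim <- range(c(x$statistic[ok], x$limit), finite = TRUE)
  graphics::plot(x$minute, x$statistic, type = "n",
                 log = if (log_y) "y" else "",
                 xlab = "minutes since operation end", ylab = x$name,
                 ylim = pmax(ylim, 1e-3), ...)
  graphics::polygon(c(x$minute, rev(x$minute)),
                    c(pmax(x$limit, 1e-3), rep(1e-3, length(x$minute))),
                    border = NA,
                    col = grDevices::adjustcolor("steelblue", 0.25))
  graphics::lines(x$minute, x$statistic, col = "grey25")
  sp <- alarm_sparks(x)
  if (nrow(sp))
    graphics::segments(sp$start, ylim[2L], sp$end, ylim[2L],
                       col = "firebrick", lwd = 3)
  invisible(x)
}

#' Plot a trajectory map
#'
#' Cohort mean with a one-SD band per signal, optionally overlaying one
#' patient's own trace.
#'
#' @param x a [trajectory_map()].
#' @param overlay optional [patient_record()] drawn on top.
#' @param signals signals to draw (default all present).
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory_map <- function(x, overlay = NULL,
                                signals = unique(x$signal), ...) {
  old <- graphics::par(mfrow = c(length(signals), 1L),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (sig in signals) {
    sub <- x[x$signal == sig & !is.na(x$mean), ]
    graphics::plot(sub$minute, sub$mean, type = "n",
                   xlab = "", ylab = sig,
                   ylim = range(c(sub$mean - sub$sd, sub$mean + sub$sd)),
                   ...)
    graphics::polygon(c(sub$minute, rev(sub$minute)),
                      c(sub$mean - sub$sd, rev(sub$mean + sub$sd)),
                      border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.3))
    graphics::lines(sub$minute, sub$mean, col = "steelblue4", lwd = 2)
    if (!is.null(overlay)) {
      tr <- overlay$traces[[sig]]
      graphics::lines(tr$minute, tr$value, col = "grey30")
    }
  }
  invisible(x)
}
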