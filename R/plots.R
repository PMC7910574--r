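#' @export
plot.sweep_result <- function(x, ...) {
  tab <- x$table
  plot(tab$pe_mmhg, tab$delta_v_cm_s, pch = 19,
       xlab = "externally applied pressure Pe (mmHg)",
       ylab = expression(Delta * v ~ "(cm/s)"),
       main = sprintf("Velocity balance sweep, ICP = %.0f mmHg", x$icp), ...)
  graphics::abline(h = 0, lty = 3)
  if (nrow(tab) >= 3) {
    fit <- stats::lm(delta_v_cm_s ~ stats::poly(pe_mmhg, 2, raw = TRUE), data = tab)
    xx <- seq(min(tab$pe_mmhg), max(tab$pe_mmhg), length.out = 200)
    graphics::lines(xx, stats::predict(fit, data.frame(pe_mmhg = xx)))
  }
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$pair_means, x$differences, pch = 1,
       xlab = "mean of paired readings (mmHg)",
       ylab = "invasive - non-invasive (mmHg)",
       main = "Bland-Altman agreement", ...)
  graphics::abline(h = x$mean_diff, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' @export
plot.monitoring_result <- function(x, ...) {
  p <- x$pairs
  ylim <- range(p$icp_inv_mmhg, p$icp_noninv_mmhg)
  plot(p$time_s / 60, p$icp_inv_mmhg, type = "l", ylim = ylim,
       xlab = "time (min)", ylab = "ICP (mmHg)",
       main = sprintf("Subject %s monitoring", x$subject), ...)
  graphics::lines(p$time_s / 60, p$icp_noninv_mmhg, col = 2)
  graphics::legend("topright", c("invasive", "non-invasive"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}
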