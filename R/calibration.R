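#' Fit a per-subject linear BFF-to-ICP calibration
#'
#' Ordinary least squares of reference (invasive) ICP on the window-mean
#' blood flow factor, giving the subject-specific calibration equation
#' \eqn{ICP = a \cdot \overline{BFF} + b} in mmHg. Because any affine
#' re-normalization of the BFF statistic is absorbed by `a` and `b`, the
#' calibrated ICP estimates are invariant to the BFF scale convention.
#'
#' @param bff Window-mean BFF values (dimensionless).
#' @param icp_ref Paired reference ICP readings (mmHg), same length.
#' @return An object of class `calibration_model` with `slope`, `intercept`,
#'   `n`, `residual_sd` (mmHg) and a `fitted_at` timestamp.
#' @examples
#' m <- fit_calibration(c(0.0, 0.1, 0.2), 56.3 * c(0.0, 0.1, 0.2) + 10.1)
#' m$slope
#' @export
fit_calibration <- function(bff, icp_ref) {
  if (length(bff) != length(icp_ref)) stop("bff and icp_ref must have equal length")
  if (length(bff) < 2) stop("at least 2 calibration points are required")
  if (length(unique(bff)) < 2)
    stop("uncalibratable: calibration BFF values are constant")
  fit <- stats::lm(icp_ref ~ bff)
  cf <- unname(stats::coef(fit))
  # summary() warns on exact (noiseless) fits; those are legitimate here
  sm <- if (length(bff) > 2) suppressWarnings(summary(fit)) else NULL
  structure(
    list(slope = cf[2], intercept = cf[1], n = length(bff),
         residual_sd = if (!is.null(sm)) sm$sigma else 0,
         slope_se = if (!is.null(sm)) sm$coefficients[2, 2] else NA_real_,
         intercept_se = if (!is.null(sm)) sm$coefficients[1, 2] else NA_real_,
         fitted_at = Sys.time()),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: ICP = %.4g x BFF + %.4g mmHg  (n = %d, residual SD %.3g mmHg)\n",
              x$slope, x$intercept, x$n, x$residual_sd))
  invisible(x)
}

#' Apply a calibration model to BFF values
#'
#' Maps BFF to non-invasive ICP in mmHg through the subject's linear
#' calibration, `icp = slope * bff + intercept`, propagating any validity
#' mask.
#'
#' @param model A [fit_calibration()] model.
#' @param bff A `bff_series` or a numeric vector.
#' @return For a `bff_series`: data frame `time_s`, `icp_noninv_mmhg`,
#'   `valid`. For a numeric vector: a numeric vector.
#' @export
apply_calibration <- function(model, bff) {
  if (inherits(bff, "bff_series")) {
    s <- bff$samples
    return(data.frame(time_s = s$time_s,
                      icp_noninv_mmhg = model$slope * s$bff + model$intercept,
                      valid = s$valid))
  }
  model$slope * bff + model$intercept
}

#' Assemble a monitoring session
#'
#' A monitoring session holds paired records at 10 s spacing: timestamp,
#' invasive reference ICP, window-mean BFF and a validity flag, for one
#' subject over up to one hour.
#'
#' @param subject Subject identifier.
#' @param time_s Timestamps (s), strictly increasing at the pairing interval.
#' @param icp_inv Invasive ICP readings (mmHg).
#' @param bff Window-mean BFF values.
#' @param valid Validity flags (default all valid).
#' @param pairing_s Pairing interval (s), 10 by default.
#' @param max_duration_s Maximum session duration (s); one hour plus one
#'   interval of tolerance by default.
#' @return An object of class `monitoring_session`.
#' @export
monitoring_session <- function(subject, time_s, icp_inv, bff, valid = NULL,
                               pairing_s = 10, max_duration_s = 3600 + pairing_s) {
  n <- length(time_s)
  stopifnot(length(icp_inv) == n, length(bff) == n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (n > 1 && any(abs(diff(time_s) - pairing_s) > 1e-6))
    stop(sprintf("timestamps must increase in exact %g s steps", pairing_s))
  if (n > 0 && (time_s[n] - time_s[1]) > max_duration_s)
    stop("session longer than the permitted monitoring duration")
  structure(
    list(subject = subject,
         records = data.frame(time_s = time_s, icp_inv_mmhg = icp_inv,
                              bff = bff, valid = valid),
         pairing_s = pairing_s),
    class = "monitoring_session"
  )
}

#' @export
print.monitoring_session <- function(x, ...) {
  r <- x$records
  cat(sprintf("monitoring_session [%s]: %d pairs at %g s spacing (%.0f s), %d masked\n",
              x$subject, nrow(r), x$pairing_s,
              if (nrow(r)) r$time_s[nrow(r)] - r$time_s[1] else 0, sum(!r$valid)))
  invisible(x)
}

#' Run continuous non-invasive monitoring against the invasive reference
#'
#' Applies a previously fitted calibration to the session's BFF values and
#' aligns the resulting non-invasive ICP with the invasive reference.
#' Optionally both series are smoothed with the same centered 60 s moving
#' average before comparison (the convention used for monitoring plots;
#' leave smoothing off when the pairs feed agreement statistics).
#'
#' @param session A [monitoring_session()].
#' @param model A [fit_calibration()] model.
#' @param smooth Smooth both series before pairing? Default `TRUE`.
#' @param smooth_window_s Moving-average window (s).
#' @return An object of class `monitoring_result`: data frame `pairs`
#'   (`time_s`, `icp_inv_mmhg`, `icp_noninv_mmhg`, `diff_mmhg`; valid
#'   records only, `diff` = invasive - non-invasive) and a `summary` list
#'   (`n`, `mean_diff`, `sd_diff`, `mean_abs_diff`, `max_abs_diff`).
#' @export
run_monitoring <- function(session, model, smooth = TRUE, smooth_window_s = 60) {
  r <- session$records
  if (!any(r$valid)) stop("session has no valid records")
  icp_noninv <- apply_calibration(model, r$bff)
  icp_inv <- r$icp_inv_mmhg
  if (smooth) {
    icp_noninv <- moving_average(icp_noninv, smooth_window_s, session$pairing_s, r$valid)
    icp_inv <- moving_average(icp_inv, smooth_window_s, session$pairing_s, r$valid)
  }
  keep <- r$valid
  d <- icp_inv[keep] - icp_noninv[keep]
  structure(
    list(pairs = data.frame(time_s = r$time_s[keep],
                            icp_inv_mmhg = icp_inv[keep],
                            icp_noninv_mmhg = icp_noninv[keep],
                            diff_mmhg = d),
         summary = list(n = sum(keep), mean_diff = mean(d), sd_diff = stats::sd(d),
                        mean_abs_diff = mean(abs(d)), max_abs_diff = max(abs(d))),
         subject = session$subject, model = model, smoothed = smooth),
    class = "monitoring_result"
  )
}

#' @export
print.monitoring_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("monitoring_result [%s]: n = %d, mean diff %.3f, SD %.3f, max |diff| %.3f mmHg%s\n",
              x$subject, s$n, s$mean_diff, s$sd_diff, s$max_abs_diff,
              if (x$smoothed) " (60 s smoothed)" else ""))
  invisible(x)
}

#' Calibrate on the initial records and monitor the remainder
#'
#' Convenience pipeline for one subject: fit the linear calibration on the
#' session's first `calib_points` valid pairs (about 5 minutes of invasive
#' readings at the default 30 points), then monitor the rest of the session
#' without recalibration.
#'
#' @param session A [monitoring_session()].
#' @param calib_points Number of initial valid pairs used for calibration.
#' @param smooth,smooth_window_s Passed to [run_monitoring()].
#' @return List with the fitted `model` and the `monitoring` result on the
#'   post-calibration remainder of the session.
#' @export
monitor_subject <- function(session, calib_points = 30, smooth = FALSE,
                            smooth_window_s = 60) {
  r <- session$records
  valid_idx <- which(r$valid)
  if (length(valid_idx) <= calib_points)
    stop("session too short: nothing left to monitor after calibration")
  cal <- valid_idx[seq_len(calib_points)]
  model <- fit_calibration(r$bff[cal], r$icp_inv_mmhg[cal])
  rest <- r[-(seq_len(max(cal))), , drop = FALSE]
  rest_session <- monitoring_session(session$subject, rest$time_s,
                                     rest$icp_inv_mmhg, rest$bff, rest$valid,
                                     pairing_s = session$pairing_s)
  list(model = model,
       monitoring = run_monitoring(rest_session, model, smooth, smooth_window_s))
}
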