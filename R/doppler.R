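#' Two-depth Doppler intensity trace
#'
#' Container for simultaneous Doppler signal-intensity series from the
#' intracranial (IOA) and extracranial (EOA) sample volumes, with a shared
#' validity mask. Intensities are in arbitrary linear units and must be
#' strictly positive wherever the mask is valid.
#'
#' @param ps_ioa,ps_eoa Intensity series (equal length).
#' @param fs_hz Sampling rate (Hz).
#' @param valid Logical validity mask (default all valid).
#' @param meta Optional list of provenance (gains, seed) for synthetic traces.
#' @return An object of class `doppler_trace`: data frame `samples`
#'   (`time_s`, `ps_ioa`, `ps_eoa`, `valid`) with the sampling rate and
#'   metadata attached.
#' @export
doppler_trace <- function(ps_ioa, ps_eoa, fs_hz, valid = NULL, meta = list()) {
  n <- length(ps_ioa)
  if (length(ps_eoa) != n) stop("both channels must have the same length")
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) stop("validity mask length mismatch")
  if (fs_hz <= 0) stop("sampling rate must be positive")
  if (any(ps_ioa[valid] <= 0) || any(ps_eoa[valid] <= 0))
    stop("valid samples must have strictly positive intensity")
  structure(
    list(samples = data.frame(time_s = (seq_len(n) - 1) / fs_hz,
                              ps_ioa = ps_ioa, ps_eoa = ps_eoa, valid = valid),
         fs_hz = fs_hz, meta = meta),
    class = "doppler_trace"
  )
}

#' @export
print.doppler_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("doppler_trace: %d samples at %g Hz (%.1f s), %d masked\n",
              n, x$fs_hz, n / x$fs_hz, sum(!x$samples$valid)))
  invisible(x)
}

#' Synthesize a Doppler intensity channel from an area series
#'
#' Models the Doppler signal intensity as proportional to the insonated
#' lumen cross-sectional area, with multiplicative Gaussian noise:
#' `Ps(t) = gain * A(t) * (1 + eps(t))`, `eps ~ N(0, noise_sd_fraction)`,
#' truncated just above -1 so the intensity stays positive. Reproducible
#' from the seed.
#'
#' @param area_mm2 Cross-sectional area series (mm^2), strictly positive.
#' @param gain Channel gain (> 0), arbitrary linear units per mm^2.
#' @param noise_sd_fraction Fractional noise SD (>= 0).
#' @param seed Integer RNG seed.
#' @return Intensity series, same length as `area_mm2`.
#' @export
synthesize_intensity <- function(area_mm2, gain = 1, noise_sd_fraction = 0,
                                 seed = 1L) {
  if (gain <= 0) stop("gain must be positive")
  stopifnot(all(area_mm2 > 0), noise_sd_fraction >= 0)
  eps <- if (noise_sd_fraction > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    pmax(stats::rnorm(length(area_mm2), 0, noise_sd_fraction), -1 + 1e-9)
  } else {
    rep(0, length(area_mm2))
  }
  gain * area_mm2 * (1 + eps)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Blood flow factor (BFF) from a two-depth Doppler trace
#'
#' Computes the blood flow factor: per consecutive window (10 s by default,
#' giving a 0.1 Hz output), the time-normalized integral of the natural
#' logarithm of the IOA/EOA intensity ratio over the window's valid samples,
#' by trapezoidal quadrature:
#' \deqn{BFF = \frac{1}{T_w}\int_w \ln\frac{P_{s,IOA}(t)}{P_{s,EOA}(t)}\,dt.}
#' The statistic is dimensionless, invariant to a common gain on both
#' channels, and antisymmetric under channel exchange. Windows with fewer
#' than half their samples valid are emitted masked rather than dropped, so
#' the 0.1 Hz time base stays regular.
#'
#' @param trace A [doppler_trace()].
#' @param window_s Window length (s); must hold at least 2 samples.
#' @return An object of class `bff_series`: data frame `samples`
#'   (`time_s` = window end time, `bff`, `valid`) plus the window length.
#' @export
compute_bff <- function(trace, window_s = 10) {
  s <- trace$samples
  nwin_samples <- round(window_s * trace$fs_hz)
  if (nwin_samples < 2) stop("window must contain at least 2 samples")
  n_windows <- floor(nrow(s) / nwin_samples)
  if (n_windows < 1) stop("trace shorter than one window")
  if (any(s$valid & (s$ps_ioa <= 0 | s$ps_eoa <= 0)))
    stop("valid samples must have strictly positive intensity")

  out_t <- numeric(n_windows); out_bff <- rep(NA_real_, n_windows)
  out_valid <- logical(n_windows)
  for (w in seq_len(n_windows)) {
    idx <- ((w - 1) * nwin_samples + 1):(w * nwin_samples)
    out_t[w] <- w * window_s
    ok <- s$valid[idx]
    if (mean(ok) < 0.5) next
    tt <- s$time_s[idx][ok]
    y <- log(s$ps_ioa[idx][ok] / s$ps_eoa[idx][ok])
    if (length(tt) == 1L) { out_bff[w] <- y; out_valid[w] <- TRUE; next }
    span <- tt[length(tt)] - tt[1]
    integral <- sum(diff(tt) * (y[-1] + y[-length(y)]) / 2)
    out_bff[w] <- integral / span
    out_valid[w] <- TRUE
  }
  structure(
    list(samples = data.frame(time_s = out_t, bff = out_bff, valid = out_valid),
         window_s = window_s),
    class = "bff_series"
  )
}

#' @export
print.bff_series <- function(x, ...) {
  cat(sprintf("bff_series: %d windows of %g s, %d masked; mean BFF %.4g\n",
              nrow(x$samples), x$window_s, sum(!x$samples$valid),
              mean(x$samples$bff[x$samples$valid])))
  invisible(x)
}

#' Mark Doppler artifacts in a two-depth trace
#'
#' Flags transducer drop-outs (samples below a small fraction of the channel
#' median) and spikes (samples deviating from a rolling median by more than
#' `spike_z` robust standard deviations, estimated by the MAD of the
#' detrended signal). A sample flagged on either channel is masked on both.
#'
#' @param trace A [doppler_trace()].
#' @param spike_z Spike threshold in robust SD units.
#' @param dropout_floor_fraction Drop-out threshold as a fraction of the
#'   channel median.
#' @param median_window_s Rolling-median window (s).
#' @return The trace with an updated mask; the number of newly masked
#'   samples is recorded in `meta$artifacts_removed`.
#' @export
artifact_filter <- function(trace, spike_z = 5, dropout_floor_fraction = 0.05,
                            median_window_s = 2) {
  s <- trace$samples
  flag_channel <- function(x) {
    med <- stats::median(x)
    dropout <- x < dropout_floor_fraction * med
    k <- round(median_window_s * trace$fs_hz)
    k <- max(3L, if (k %% 2 == 0) k + 1L else k)
    k <- min(k, if (nrow(s) %% 2 == 0) nrow(s) - 1L else nrow(s))
    roll <- stats::runmed(x, k, endrule = "median")
    resid <- x - roll
    sd_rob <- max(stats::mad(resid), 1e-12 * abs(med))
    spike <- abs(resid) > spike_z * sd_rob
    dropout | spike
  }
  bad <- flag_channel(s$ps_ioa) | flag_channel(s$ps_eoa)
  new_valid <- s$valid & !bad
  removed <- sum(s$valid & !new_valid)
  out <- trace
  out$samples$valid <- new_valid
  out$meta$artifacts_removed <- removed
  out
}

#' Centered moving average with mask propagation
#'
#' Smooths a uniformly sampled series with a centered moving mean over the
#' valid samples inside the window; at the edges the available partial
#' window is used, so the output has the same length as the input. The
#' validity mask is carried through unchanged.
#'
#' @param series A `bff_series`, or a numeric vector.
#' @param window_s Window length (s); 60 s by default.
#' @param dt_s Sample spacing (s); taken from the series when it carries one.
#' @param valid Optional mask for the numeric-vector form.
#' @return Same type as the input, smoothed.
#' @export
moving_average <- function(series, window_s = 60, dt_s = NULL, valid = NULL) {
  if (inherits(series, "bff_series")) {
    dt_s <- diff(series$samples$time_s[1:2])
    out <- series
    out$samples$bff <- moving_average(series$samples$bff, window_s, dt_s,
                                      series$samples$valid)
    return(out)
  }
  x <- series
  if (length(x) == 0) stop("empty series")
  if (is.null(dt_s)) stop("dt_s is required for a bare numeric series")
  if (is.null(valid)) valid <- rep(TRUE, length(x))
  halfn <- floor(window_s / (2 * dt_s))
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1, i - halfn):min(n, i + halfn)
    ok <- valid[idx] & !is.na(x[idx])
    if (any(ok)) out[i] <- mean(x[idx][ok])
  }
  out
}
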