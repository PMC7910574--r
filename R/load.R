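#' Pressure loading of the ophthalmic artery
#'
#' Bundles the pressures acting on the vessel: the intracranial pressure (ICP)
#' compressing the intracranial segment, the intraorbital tissue pressure
#' (Pio) and any externally applied orbital pressure (Pe) compressing the
#' extracranial segment, the pulsatile inlet pressure waveform, and the
#' resistive outlet termination.
#'
#' @param icp Intracranial pressure (mmHg, >= 0).
#' @param pio Intraorbital pressure (mmHg, >= 0); 4 mmHg by default.
#' @param pe Externally applied orbital pressure (mmHg, >= 0); 0 means not
#'   applied, as during continuous monitoring.
#' @param inlet_mean Cycle-mean inlet pressure (mmHg).
#' @param inlet_amplitude Peak-to-peak pulse amplitude of the inlet waveform
#'   (mmHg); must be smaller than `inlet_mean`.
#' @param period Cardiac period (s).
#' @param waveform Waveform shape id: `"rect_sine"` (rectified sinusoid plus
#'   mean, the default), `"sine"`, or `"constant"`.
#' @param outlet_resistance Terminal resistance at the outlet
#'   (mmHg s/mL), referenced to zero distal pressure. The default 223.5 is
#'   calibrated once so the steady mean flow yields a mean probe velocity of
#'   about 16.8 cm/s and an analytic inter-probe Poiseuille drop of about
#'   1.225 mmHg.
#' @return An object of class `pressure_load`.
#' @examples
#' load <- pressure_load(icp = 20, pe = 14)
#' inlet_pressure_waveform(seq(0, 1, by = 0.1), load)
#' @export
pressure_load <- function(icp, pio = 4, pe = 0,
                          inlet_mean = 60, inlet_amplitude = 20,
                          period = 1.0, waveform = "rect_sine",
                          outlet_resistance = 223.5) {
  if (icp < 0 || pio < 0 || pe < 0) stop("icp, pio and pe must be non-negative")
  if (period <= 0) stop("cardiac period must be positive")
  if (inlet_mean <= inlet_amplitude)
    stop("mean inlet pressure must exceed the pulse amplitude (no negative inlet pressure)")
  if (outlet_resistance <= 0) stop("outlet resistance must be positive")
  waveform <- match.arg(waveform, c("rect_sine", "sine", "constant"))
  structure(
    list(icp = icp, pio = pio, pe = pe,
         inlet_mean = inlet_mean, inlet_amplitude = inlet_amplitude,
         period = period, waveform = waveform,
         outlet_resistance = outlet_resistance),
    class = "pressure_load"
  )
}

#' @export
print.pressure_load <- function(x, ...) {
  cat(sprintf("Pressure load: ICP %.1f, Pio %.1f, Pe %.1f mmHg\n", x$icp, x$pio, x$pe))
  cat(sprintf("inlet %s: mean %.1f, amplitude %.1f mmHg, period %.3f s; outlet R %.1f mmHg.s/mL\n",
              x$waveform, x$inlet_mean, x$inlet_amplitude, x$period, x$outlet_resistance))
  invisible(x)
}

#' Inlet pressure waveform
#'
#' Periodic inlet pressure (mmHg) at time `t` for the given load. The default
#' shape is a rectified sinusoid recentred on the configured mean: a fast
#' systolic peak and a broad diastolic trough, with the cycle mean equal to
#' `inlet_mean` exactly and the peak-to-trough excursion equal to
#' `inlet_amplitude`. The minimum never falls below `inlet_mean -
#' inlet_amplitude`.
#'
#' @param t Time (s), scalar or vector, non-negative.
#' @param load A [pressure_load()].
#' @return Inlet pressure (mmHg), same length as `t`.
#' @export
inlet_pressure_waveform <- function(t, load) {
  if (any(t < 0)) stop("t must be non-negative")
  mean_p <- load$inlet_mean
  amp <- load$inlet_amplitude
  phase <- (t %% load$period) / load$period
  switch(load$waveform,
    constant = rep(mean_p, length(t)),
    sine = mean_p + (amp / 2) * sin(2 * pi * phase),
    rect_sine = mean_p + amp * (abs(sin(pi * phase)) - 2 / pi)
  )
}

#' External pressure along the vessel
#'
#' The compressive tissue pressure acting on the outer wall at position `x`:
#' ICP over the intracranial segment, the sum Pio + Pe over the extracranial
#' segment (intraorbital pressure plus any externally applied pressure), and
#' 0 by convention inside the rigid optic canal, where the wall load cannot
#' affect the lumen.
#'
#' @param x Position along the vessel (mm), in `[0, total_length]`.
#' @param geom An [oa_geometry()].
#' @param load A [pressure_load()].
#' @return External pressure (mmHg), same length as `x`.
#' @examples
#' g <- oa_geometry()
#' external_pressure_at(c(5, 12, 22), g, pressure_load(icp = 20, pe = 10))
#' @export
external_pressure_at <- function(x, geom, load) {
  reg <- region_at(x, geom)
  out <- numeric(length(x))
  out[reg == "ioa"] <- load$icp
  out[reg == "eoa"] <- load$pio + load$pe
  out
}
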