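#' Extract a Doppler-probe series from a simulated field
#'
#' Averages velocity, area and pressure over the probe vicinity (measurement
#' location +/- the geometry's probe half-width) at each time moment of the
#' final simulated cardiac cycle, emulating the lumen-cross-section-and-
#' vicinity averaging applied to the two-depth Doppler sample volumes.
#'
#' @param field A `hemo_field` from [simulate_oa()].
#' @param geom The geometry used for the simulation.
#' @param location `"ioa"` or `"eoa"`.
#' @return An object of class `probe_series`: list with `location`, a
#'   `samples` data frame (`time_s`, `velocity_cm_s`, `area_mm2`,
#'   `pressure_mmhg`; one row per time moment of the final cycle) and the
#'   cycle averages `mean_velocity_cm_s`, `mean_area_mm2`, `mean_pressure_mmhg`.
#' @examples
#' \donttest{
#' f <- simulate_oa(oa_geometry(), pressure_load(icp = 20, pe = 14))
#' probe(f, location = "ioa")$mean_velocity_cm_s
#' }
#' @export
probe <- function(field, geom = field$geometry, location = c("ioa", "eoa")) {
  location <- match.arg(location)
  x0 <- if (location == "ioa") geom$probe_ioa else geom$probe_eoa
  h <- geom$probe_halfwidth
  reg <- geom$regions[geom$regions$region == location, ]
  if (x0 - h < reg$x0 || x0 + h > reg$x1)
    stop("probe vicinity extends outside its region")
  cols <- which(field$x_mm >= x0 - h & field$x_mm <= x0 + h)
  final <- field$config$n_cycles
  rows <- which(field$cycle == final)
  samples <- data.frame(
    time_s = field$time_s[rows],
    velocity_cm_s = rowMeans(field$velocity_cm_s[rows, cols, drop = FALSE]),
    area_mm2 = rowMeans(field$area_mm2[rows, cols, drop = FALSE]),
    pressure_mmhg = rowMeans(field$pressure_mmhg[rows, cols, drop = FALSE])
  )
  structure(
    list(location = location, samples = samples,
         mean_velocity_cm_s = mean(samples$velocity_cm_s),
         mean_area_mm2 = mean(samples$area_mm2),
         mean_pressure_mmhg = mean(samples$pressure_mmhg)),
    class = "probe_series"
  )
}

#' @export
print.probe_series <- function(x, ...) {
  cat(sprintf("probe_series [%s]: %d moments; mean v %.3f cm/s, mean A %.4f mm2, mean p %.2f mmHg\n",
              toupper(x$location), nrow(x$samples),
              x$mean_velocity_cm_s, x$mean_area_mm2, x$mean_pressure_mmhg))
  invisible(x)
}
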