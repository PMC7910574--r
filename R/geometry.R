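#' Segmented ophthalmic artery geometry
#'
#' Builds the idealized straight ophthalmic artery (OA) used throughout the
#' package: three contiguous regions from inlet to outlet — the intracranial
#' segment (IOA), the bony optic canal (rigid), and the extracranial segment
#' (EOA) — with per-region reference radius and wall compliance, and one
#' Doppler measurement location inside each compliant segment.
#'
#' Called with no arguments it returns the canonical default geometry: a
#' 30 mm vessel (IOA 0–10 mm, canal 10–14 mm, EOA 14–30 mm), uniform lumen
#' radius 0.7 mm, probes at 5 mm and 22 mm (inter-probe distance 17 mm), and
#' compliance 3e-4 per mmHg in the compliant segments.  With the default mean
#' flow these values give an analytic inter-probe Hagen–Poiseuille pressure
#' drop of about 1.2 mmHg.
#'
#' @param ioa_end End of the intracranial segment (mm from the inlet).
#' @param canal_end End of the optic canal (mm); the EOA runs from here to
#'   `total_length`.
#' @param total_length Total vessel length (mm).
#' @param radius Reference lumen radius per region (mm); scalar or named
#'   vector `c(ioa=, canal=, eoa=)`.
#' @param compliance Fractional area change per mmHg of transmural pressure,
#'   per region. The canal entry must be 0 (rigid bone).
#' @param probe_ioa,probe_eoa Measurement locations (mm), strictly inside the
#'   IOA and EOA regions respectively.
#' @param probe_halfwidth Half-width (mm) of the probe vicinity over which
#'   velocity and area are averaged.
#'
#' @return An object of class `oa_geometry`: a list with a `regions`
#'   data frame (`region`, `x0`, `x1`, `radius_mm`, `compliance_per_mmhg`),
#'   probe locations, and the probe half-width.
#' @examples
#' geom <- oa_geometry()
#' geom$regions
#' poiseuille_pressure_drop(geom, flow_ml_s = 0.259)
#' @export
oa_geometry <- function(ioa_end = 10, canal_end = 14, total_length = 30,
                        radius = c(ioa = 0.7, canal = 0.7, eoa = 0.7),
                        compliance = c(ioa = 3e-4, canal = 0, eoa = 3e-4),
                        probe_ioa = 5, probe_eoa = 22,
                        probe_halfwidth = 1) {
  expand3 <- function(v, what) {
    if (length(v) == 1L) v <- c(ioa = unname(v), canal = unname(v), eoa = unname(v))
    if (is.null(names(v))) names(v) <- c("ioa", "canal", "eoa")
    if (!all(c("ioa", "canal", "eoa") %in% names(v)))
      stop(sprintf("'%s' must be named for regions ioa, canal, eoa", what))
    v[c("ioa", "canal", "eoa")]
  }
  radius <- expand3(radius, "radius")
  compliance <- expand3(compliance, "compliance")

  regions <- data.frame(
    region = c("ioa", "canal", "eoa"),
    x0 = c(0, ioa_end, canal_end),
    x1 = c(ioa_end, canal_end, total_length),
    radius_mm = unname(radius),
    compliance_per_mmhg = unname(compliance),
    stringsAsFactors = FALSE
  )
  geom <- structure(
    list(regions = regions, total_length = total_length,
         probe_ioa = probe_ioa, probe_eoa = probe_eoa,
         probe_halfwidth = probe_halfwidth),
    class = "oa_geometry"
  )
  validate_oa_geometry(geom)
}

validate_oa_geometry <- function(geom) {
  r <- geom$regions
  if (!(0 < r$x1[1] && r$x1[1] < r$x1[2] && r$x1[2] < r$x1[3]))
    stop("regions must be contiguous and ordered: 0 < ioa_end < canal_end < total_length")
  if (any(r$radius_mm <= 0)) stop("all radii must be positive")
  if (any(r$compliance_per_mmhg < 0)) stop("compliances must be non-negative")
  if (r$compliance_per_mmhg[r$region == "canal"] != 0)
    stop("the optic canal is rigid: its compliance must be 0")
  if (geom$probe_halfwidth <= 0) stop("probe_halfwidth must be positive")
  h <- geom$probe_halfwidth
  ioa <- r[r$region == "ioa", ]
  eoa <- r[r$region == "eoa", ]
  if (!(geom$probe_ioa - h >= ioa$x0 && geom$probe_ioa + h <= ioa$x1))
    stop("IOA probe vicinity must lie strictly inside the IOA region")
  if (!(geom$probe_eoa - h >= eoa$x0 && geom$probe_eoa + h <= eoa$x1))
    stop("EOA probe vicinity must lie strictly inside the EOA region")
  geom
}

#' @export
print.oa_geometry <- function(x, ...) {
  cat("Ophthalmic artery geometry (", x$total_length, " mm)\n", sep = "")
  print(x$regions, row.names = FALSE)
  cat(sprintf("probes: IOA at %.1f mm, EOA at %.1f mm (+/- %.1f mm vicinity)\n",
              x$probe_ioa, x$probe_eoa, x$probe_halfwidth))
  invisible(x)
}

# region id ("ioa"/"canal"/"eoa") for each x (mm); boundary points are
# assigned to the downstream region except the outlet.
region_at <- function(x, geom) {
  r <- geom$regions
  if (any(x < 0 | x > geom$total_length)) stop("x outside the vessel")
  idx <- findInterval(x, c(r$x0, geom$total_length), rightmost.closed = TRUE)
  idx[idx > 3L] <- 3L
  r$region[idx]
}

#' Analytic Hagen–Poiseuille pressure drop between the two probes
#'
#' Evaluates the laminar-flow pressure loss \eqn{\Delta P = 8\mu L Q/(\pi r^4)}
#' accumulated between the IOA and EOA measurement locations, segment by
#' segment (so regions with different radii are handled), and returns it in
#' mmHg. This is the a-priori-known blood-pressure-gradient component of the
#' snapshot measurement's systematic error.
#'
#' @param geom An [oa_geometry()].
#' @param flow_ml_s Volumetric flow rate (mL/s), typically the simulated
#'   cycle-averaged inlet flow. Must be non-negative.
#' @param viscosity_pa_s Blood dynamic viscosity (Pa s).
#' @return Pressure drop in mmHg (0 when `flow_ml_s` is 0).
#' @examples
#' poiseuille_pressure_drop(oa_geometry(), 0.2588)
#' @export
poiseuille_pressure_drop <- function(geom, flow_ml_s, viscosity_pa_s = 3.5e-3) {
  stopifnot(flow_ml_s >= 0)
  q <- flow_ml_s * ML_S_TO_M3_S
  x_lo <- geom$probe_ioa
  x_hi <- geom$probe_eoa
  r <- geom$regions
  dp_pa <- 0
  for (i in seq_len(nrow(r))) {
    seg_lo <- max(x_lo, r$x0[i])
    seg_hi <- min(x_hi, r$x1[i])
    if (seg_hi > seg_lo) {
      len_m <- (seg_hi - seg_lo) * MM_TO_M
      rad_m <- r$radius_mm[i] * MM_TO_M
      dp_pa <- dp_pa + 8 * viscosity_pa_s * len_m * q / (pi * rad_m^4)
    }
  }
  dp_pa / MMHG_TO_PA
}
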