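#' Algebraic tube law: cross-sectional area from transmural pressure
#'
#' Relates the lumen cross-sectional area to the transmural pressure
#' (intraluminal minus external) through an exponential-softening law
#' \eqn{A = A_{ref}\, g(c\,(p - p_{ext}))} with \eqn{g(s) = e^s} blended
#' smoothly into a collapse floor at `floor_fraction * A_ref`, so the area
#' stays positive under arbitrarily strong compression. `g` is smooth and
#' strictly increasing wherever the compliance is positive, with
#' `g(0) = 1` and slope `dA/dp = A_ref * c` at zero transmural pressure.
#' A rigid region (`compliance = 0`) returns the reference area regardless
#' of pressure.
#'
#' @param p_lumen Intraluminal pressure (mmHg).
#' @param p_ext External (tissue) pressure (mmHg).
#' @param area_ref_mm2 Reference area at zero transmural pressure (mm^2).
#' @param compliance_per_mmhg Fractional area change per mmHg (>= 0).
#' @param floor_fraction Collapse floor as a fraction of the reference area.
#' @return Cross-sectional area (mm^2), vectorized over the pressures.
#' @examples
#' tube_law_area(60, 20, area_ref_mm2 = 1.539, compliance_per_mmhg = 3e-4)
#' @export
tube_law_area <- function(p_lumen, p_ext, area_ref_mm2, compliance_per_mmhg,
                          floor_fraction = 0.05) {
  stopifnot(compliance_per_mmhg >= 0, area_ref_mm2 > 0,
            floor_fraction > 0, floor_fraction < 1)
  if (compliance_per_mmhg == 0) {
    return(rep(area_ref_mm2, length.out = max(length(p_lumen), length(p_ext))))
  }
  s <- compliance_per_mmhg * (p_lumen - p_ext)
  area_ref_mm2 * tube_law_g(s, floor_fraction)
}

# Smooth-max blend of exp(s) with the collapse floor:
# g(s) = (exp(k s) + f^k)^(1/k), evaluated in log space for stability.
# k = 8 keeps the perturbation at s = 0 below 2e-6 of A_ref for f = 0.05.
tube_law_g <- function(s, floor_fraction, k = 8) {
  a <- k * s
  b <- k * log(floor_fraction)
  m <- pmax(a, b)
  exp((m + log(exp(a - m) + exp(b - m))) / k)
}

# d g / d s, matching tube_law_g
tube_law_dg <- function(s, floor_fraction, k = 8) {
  a <- k * s
  b <- k * log(floor_fraction)
  m <- pmax(a, b)
  g <- exp((m + log(exp(a - m) + exp(b - m))) / k)
  w <- exp(a - m) / (exp(a - m) + exp(b - m))
  g * w
}
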