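#' Sweep the externally applied pressure and record the velocity difference
#'
#' Runs one simulation per value of the externally applied orbital pressure
#' Pe at fixed ICP and Pio, and records \eqn{\Delta v}: the cycle-averaged
#' IOA probe velocity minus the cycle-averaged EOA probe velocity. The Pe at
#' which \eqn{\Delta v} crosses zero is the balance point of the snapshot
#' measurement, which approximates ICP minus the known systematic components
#' (intraorbital pressure and arterial pressure gradient).
#'
#' @param icp Intracranial pressure (mmHg).
#' @param pio Intraorbital pressure (mmHg).
#' @param pe_grid Increasing grid of Pe values (mmHg); 0, 2, ..., 34 by
#'   default.
#' @param geom An [oa_geometry()].
#' @param config A [sim_config()].
#' @param base_load A [pressure_load()] providing the inlet waveform and
#'   outlet resistance; its `icp`, `pio`, `pe` are overridden per run.
#' @param on_error `"stop"` (default) aborts on a diverged run; `"drop"`
#'   excludes the failed Pe values with a warning.
#' @return An object of class `sweep_result`: data frame `table`
#'   (`pe_mmhg`, `delta_v_cm_s`, `mean_flow_ml_s`), plus `icp`, `pio` and
#'   (after [find_balance_pe()]) the fitted polynomial coefficients.
#' @examples
#' \donttest{
#' sw <- sweep_pe(icp = 20, pe_grid = seq(10, 18, by = 4))
#' sw$table
#' }
#' @export
sweep_pe <- function(icp, pio = 4, pe_grid = seq(0, 34, by = 2),
                     geom = oa_geometry(), config = sim_config(),
                     base_load = pressure_load(icp = icp, pio = pio),
                     on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  if (length(pe_grid) == 0 || is.unsorted(pe_grid, strictly = TRUE))
    stop("pe_grid must be non-empty and strictly increasing")
  rows <- lapply(pe_grid, function(pe) {
    load <- base_load
    load$icp <- icp; load$pio <- pio; load$pe <- pe
    res <- tryCatch({
      f <- simulate_oa(geom, load, config)
      data.frame(pe_mmhg = pe,
                 delta_v_cm_s = probe(f, geom, "ioa")$mean_velocity_cm_s -
                                probe(f, geom, "eoa")$mean_velocity_cm_s,
                 mean_flow_ml_s = f$meta$mean_inlet_flow_ml_s)
    }, error = function(e) e)
    res
  })
  failed <- vapply(rows, inherits, logical(1), "error")
  if (any(failed)) {
    msg <- sprintf("simulation diverged at Pe = %s mmHg",
                   paste(pe_grid[failed], collapse = ", "))
    if (on_error == "stop") stop(msg)
    warning(paste(msg, "- excluded from the sweep"))
    rows <- rows[!failed]
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, icp = icp, pio = pio, fit_coefficients = NULL),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Pe sweep at ICP %.1f, Pio %.1f mmHg (%d points)\n",
              x$icp, x$pio, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Locate the velocity-balance point of a Pe sweep
#'
#' Fits a low-order polynomial to the (Pe, \eqn{\Delta v}) points of a sweep
#' and returns the root inside the sweep span: the balance Pe at which the
#' cycle-averaged IOA and EOA probe velocities are equal. When the fitted
#' polynomial has several roots in range, the one nearest the sign change of
#' the raw data is taken.
#'
#' @param sweep A [sweep_pe()] result whose \eqn{\Delta v} changes sign on
#'   the grid.
#' @param order Polynomial order; 2 by default, reduced to 1 when fewer than
#'   4 sweep points are available.
#' @param tol Root tolerance (mmHg).
#' @return The balance Pe (mmHg).
#' @export
find_balance_pe <- function(sweep, order = 2, tol = 0.01) {
  tab <- sweep$table
  dv <- tab$delta_v_cm_s
  pe <- tab$pe_mmhg
  sgn <- sign(dv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0 | sgn[-length(sgn)] == 0)
  if (length(flips) == 0 && all(sgn != 0))
    stop("balance outside sweep range: delta-v does not change sign on the grid")
  raw_cross <- if (length(flips) > 0) mean(pe[c(flips[1], flips[1] + 1)]) else pe[sgn == 0][1]

  if (nrow(tab) < 4) order <- min(order, 1)
  fit <- stats::lm(dv ~ stats::poly(pe, degree = order, raw = TRUE))
  coefs <- stats::coef(fit)
  roots <- polyroot(coefs)
  real_roots <- Re(roots)[abs(Im(roots)) < 1e-8]
  in_range <- real_roots[real_roots >= min(pe) - tol & real_roots <= max(pe) + tol]
  if (length(in_range) == 0) {
    # fall back to linear interpolation across the raw sign change
    i <- flips[1]
    return(pe[i] + (pe[i + 1] - pe[i]) * dv[i] / (dv[i] - dv[i + 1]))
  }
  in_range[which.min(abs(in_range - raw_cross))]
}

#' Decompose the snapshot systematic error
#'
#' Splits the total balance offset (ICP minus the balance Pe) into its
#' a-priori-known components — the intraorbital pressure and the analytic
#' Hagen–Poiseuille inter-probe pressure gradient — and the residual
#' patient-specific component that closes the sum exactly.
#'
#' @param icp True (or reference) ICP of the sweep (mmHg).
#' @param balance_pe Balance Pe from [find_balance_pe()] (mmHg).
#' @param pio Intraorbital pressure used in the sweep (mmHg).
#' @param geom The geometry (for the gradient term).
#' @param mean_flow_ml_s Cycle-averaged flow (mL/s), typically the simulated
#'   inlet flow of the run nearest the balance point.
#' @return An object of class `error_decomposition` with fields
#'   `balance_pe`, `total_offset`, `pio_component`, `gradient_component`,
#'   `residual` (all mmHg); the three components sum to `total_offset`
#'   bit-exactly.
#' @export
decompose_error <- function(icp, balance_pe, pio, geom = oa_geometry(),
                            mean_flow_ml_s) {
  stopifnot(is.finite(balance_pe))
  total <- icp - balance_pe
  grad <- poiseuille_pressure_drop(geom, mean_flow_ml_s)
  structure(
    list(icp = icp, balance_pe = balance_pe, total_offset = total,
         pio_component = pio, gradient_component = grad,
         residual = total - pio - grad),
    class = "error_decomposition"
  )
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat(sprintf("Snapshot error decomposition (ICP %.1f mmHg):\n", x$icp))
  cat(sprintf("  balance Pe        %7.3f mmHg\n", x$balance_pe))
  cat(sprintf("  total offset      %7.3f mmHg\n", x$total_offset))
  cat(sprintf("  intraorbital      %7.3f mmHg\n", x$pio_component))
  cat(sprintf("  pressure gradient %7.3f mmHg\n", x$gradient_component))
  cat(sprintf("  residual          %7.3f mmHg\n", x$residual))
  invisible(x)
}

#' Corrected snapshot ICP estimate
#'
#' The non-invasive snapshot estimate after adding back the known systematic
#' components to the measured balance pressure: `balance_pe + pio +
#' gradient`. Its error with respect to the true ICP equals the
#' patient-specific residual of [decompose_error()] by construction.
#'
#' @param balance_pe Balance Pe (mmHg).
#' @param pio Intraorbital pressure (mmHg).
#' @param gradient Inter-probe pressure gradient (mmHg).
#' @return Estimated ICP (mmHg).
#' @examples
#' snapshot_estimate_icp(14, 4, 1.25)
#' @export
snapshot_estimate_icp <- function(balance_pe, pio, gradient) {
  stopifnot(is.finite(balance_pe), is.finite(pio), is.finite(gradient))
  balance_pe + pio + gradient
}
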