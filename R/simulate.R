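#' Numerical configuration for the vessel simulation
#'
#' @param dt Time step (s); 0.004 s by default, i.e. 250 samples per 1 s
#'   cardiac cycle.
#' @param samples_per_cycle Time moments per cardiac cycle; `dt *
#'   samples_per_cycle` must equal the cardiac period of the load.
#' @param n_cycles Number of cardiac cycles to simulate (>= 2; 3 by default,
#'   so cycle-to-cycle convergence can be assessed).
#' @param ramp_cycles Number of initial cycles over which ICP, Pio, Pe and the
#'   inlet pulse amplitude are ramped linearly from zero.
#' @param n_nodes Spatial nodes along the vessel.
#' @param density Blood density (kg/m^3).
#' @param viscosity Blood dynamic viscosity (Pa s).
#' @param tol Relative cycle-convergence tolerance used for reporting
#'   (default 1e-4, i.e. 0.01 %).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.004, samples_per_cycle = 250, n_cycles = 3,
                       ramp_cycles = 1, n_nodes = 61,
                       density = 1050, viscosity = 3.5e-3, tol = 1e-4) {
  stopifnot(dt > 0, samples_per_cycle >= 2, n_nodes >= 5,
            density > 0, viscosity > 0, tol > 0)
  if (n_cycles < 2) stop("at least 2 cycles are required for a convergence check")
  if (ramp_cycles < 1 || ramp_cycles >= n_cycles)
    stop("ramp_cycles must be >= 1 and leave at least one settled cycle")
  structure(list(dt = dt, samples_per_cycle = samples_per_cycle,
                 n_cycles = n_cycles, ramp_cycles = ramp_cycles,
                 n_nodes = n_nodes, density = density, viscosity = viscosity,
                 tol = tol),
            class = "sim_config")
}

#' Simulate pulsatile flow in the compliant ophthalmic artery
#'
#' Solves the one-dimensional cross-sectionally averaged mass and momentum
#' equations for the segmented ophthalmic artery, with a Poiseuille friction
#' closure, the algebraic tube law coupling area to transmural pressure, a
#' pulsatile pressure inlet and a resistive outlet. Time stepping is
#' semi-implicit (backward Euler with the compliance and friction
#' coefficients frozen at the previous state), which reduces each step to a
#' tridiagonal solve and is unconditionally stable; the rigid optic canal
#' (zero compliance) is handled naturally as a flux-continuity constraint.
#'
#' During the first `ramp_cycles` cycles all acting pressures (ICP, Pio, Pe)
#' and the inlet pulse amplitude are ramped linearly from zero to their
#' prescribed values; the inlet mean pressure is held from the start.
#'
#' @param geom An [oa_geometry()].
#' @param load A [pressure_load()].
#' @param config A [sim_config()]; `dt * samples_per_cycle` must equal the
#'   load's cardiac period.
#' @return An object of class `hemo_field`: list with `time_s` (length
#'   `n_cycles * samples_per_cycle + 1`), `x_mm` (length `n_nodes`), matrices
#'   `area_mm2`, `velocity_cm_s`, `pressure_mmhg` (time by space), `cycle`
#'   (cycle index per time point, 0 for the initial state), per-step inlet
#'   and outlet flows (mL/s), and a `meta` list with the cycle-convergence
#'   metric and the final-cycle volume-conservation imbalance.
#' @examples
#' \donttest{
#' f <- simulate_oa(oa_geometry(), pressure_load(icp = 20, pe = 14), sim_config())
#' f$meta$convergence
#' }
#' @export
simulate_oa <- function(geom, load, config = sim_config()) {
  if (abs(config$dt * config$samples_per_cycle - load$period) > 1e-9)
    stop("dt * samples_per_cycle must equal the cardiac period")

  n <- config$n_nodes
  L <- geom$total_length * MM_TO_M
  dx <- L / (n - 1)
  x_mm <- seq(0, geom$total_length, length.out = n)
  reg <- region_at(x_mm, geom)
  rmap <- match(reg, geom$regions$region)
  a_ref <- pi * (geom$regions$radius_mm[rmap] * MM_TO_M)^2       # m^2
  c_pa <- geom$regions$compliance_per_mmhg[rmap] / MMHG_TO_PA    # 1/Pa
  floor_frac <- 0.05

  rho <- config$density
  mu <- config$viscosity
  dt <- config$dt
  r_out <- load$outlet_resistance * RES_MMHG_ML_TO_SI            # Pa.s/m^3

  # base external pressure profile (Pa), scaled by the ramp factor in time
  p_ext_base <- external_pressure_at(x_mm, geom, load) * MMHG_TO_PA

  # control volume length per node (half cells at the ends)
  vol_len <- rep(dx, n)
  vol_len[c(1, n)] <- dx / 2

  n_steps <- config$n_cycles * config$samples_per_cycle
  ramp_time <- config$ramp_cycles * load$period

  # initial state: steady rigid-tube estimate at the mean inlet pressure,
  # zero external load (consistent with ramp factor 0 at t = 0)
  p_in0 <- load$inlet_mean * MMHG_TO_PA
  r_visc_cell <- 8 * pi * mu * dx / (0.5 * (a_ref[-n] + a_ref[-1]))^2
  q0 <- p_in0 / (r_out + sum(r_visc_cell))
  p <- p_in0 - c(0, cumsum(r_visc_cell)) * q0
  q_if <- rep(q0, n - 1)                        # interface flows, m^3/s
  area <- a_ref * tube_law_g(c_pa * p, floor_frac)
  area[c_pa == 0] <- a_ref[c_pa == 0]

  nt <- n_steps + 1
  P <- matrix(NA_real_, nt, n)
  A <- matrix(NA_real_, nt, n)
  V <- matrix(NA_real_, nt, n)
  q_in_series <- numeric(nt)
  q_out_series <- numeric(nt)

  node_velocity <- function(q_if, q_out, area) {
    qn <- c(q_if[1], 0.5 * (q_if[-(n - 1)] + q_if[-1]), q_out)
    qn / area
  }

  P[1, ] <- p
  A[1, ] <- area
  q_out0 <- p[n] / r_out
  V[1, ] <- node_velocity(q_if, q_out0, area)
  q_in_series[1] <- q_if[1]
  q_out_series[1] <- q_out0

  p_ext_prev <- 0 * p_ext_base
  collapse_warned <- FALSE

  for (k in seq_len(n_steps)) {
    t_new <- k * dt
    ramp <- min(t_new / ramp_time, 1)
    p_ext <- ramp * p_ext_base
    p_in <- (load$inlet_mean +
               ramp * (inlet_pressure_waveform(t_new, load) - load$inlet_mean)) * MMHG_TO_PA

    # linearized compliance dA/dp at the current state (per Pa)
    s <- c_pa * (p - p_ext_prev)
    comp <- a_ref * tube_law_dg(s, floor_frac) * c_pa
    comp[c_pa == 0] <- 0

    a_if <- 0.5 * (area[-n] + area[-1])
    alpha <- 1 / (1 + dt * 8 * pi * mu / (rho * a_if))
    gamma <- alpha * dt * a_if / (rho * dx)

    # tridiagonal system for p^{n+1}
    diag_b <- numeric(n); sub_a <- numeric(n); sup_c <- numeric(n); rhs <- numeric(n)
    cap <- vol_len * comp / dt
    dpe <- p_ext - p_ext_prev

    diag_b[1] <- 1; sup_c[1] <- 0; rhs[1] <- p_in
    i <- 2:(n - 1)
    sub_a[i] <- -gamma[i - 1]
    sup_c[i] <- -gamma[i]
    diag_b[i] <- cap[i] + gamma[i] + gamma[i - 1]
    rhs[i] <- cap[i] * (p[i] + dpe[i]) - alpha[i] * q_if[i] + alpha[i - 1] * q_if[i - 1]
    sub_a[n] <- -gamma[n - 1]
    diag_b[n] <- cap[n] + 1 / r_out + gamma[n - 1]
    rhs[n] <- cap[n] * (p[n] + dpe[n]) + alpha[n - 1] * q_if[n - 1]

    p_new <- thomas_solve(sub_a, diag_b, sup_c, rhs)
    if (any(!is.finite(p_new)))
      stop(sprintf("solver divergence at t = %.3f s (step %d): non-finite pressure; try a smaller dt or fewer nodes", t_new, k))

    q_if <- alpha * q_if - gamma * (p_new[-1] - p_new[-n])
    p <- p_new
    area <- a_ref * tube_law_g(c_pa * (p - p_ext), floor_frac)
    area[c_pa == 0] <- a_ref[c_pa == 0]

    if (!collapse_warned && any(area < 1.2 * floor_frac * a_ref)) {
      warning(sprintf("collapse floor saturation at t = %.3f s: lumen area within 20%% of the floor", t_new))
      collapse_warned <- TRUE
    }

    q_out <- p[n] / r_out
    P[k + 1, ] <- p
    A[k + 1, ] <- area
    V[k + 1, ] <- node_velocity(q_if, q_out, area)
    q_in_series[k + 1] <- q_if[1]
    q_out_series[k + 1] <- q_out
    p_ext_prev <- p_ext
  }

  spc <- config$samples_per_cycle
  cycle <- c(0L, rep(seq_len(config$n_cycles), each = spc))
  field <- structure(
    list(time_s = seq(0, by = dt, length.out = nt),
         x_mm = x_mm,
         area_mm2 = A / MM2_TO_M2,
         velocity_cm_s = V * M_S_TO_CM_S,
         pressure_mmhg = P / MMHG_TO_PA,
         cycle = cycle,
         inlet_flow_ml_s = q_in_series / ML_S_TO_M3_S,
         outlet_flow_ml_s = q_out_series / ML_S_TO_M3_S,
         geometry = geom, load = load, config = config,
         meta = list()),
    class = "hemo_field"
  )
  field$meta$convergence <- if (config$n_cycles >= 3) cycle_convergence(field, geom) else NA_real_
  field$meta$conservation <- conservation_imbalance(field)
  field$meta$mean_inlet_flow_ml_s <- mean(field$inlet_flow_ml_s[cycle == config$n_cycles])
  field
}

# Thomas algorithm for a tridiagonal system; a = sub-diagonal (a[1] unused),
# b = diagonal, c = super-diagonal (c[n] unused).
thomas_solve <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]
  dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- if (i < n) c[i] / m else 0
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' @export
print.hemo_field <- function(x, ...) {
  cat(sprintf("hemo_field: %d time points x %d nodes, %d cycles\n",
              length(x$time_s), length(x$x_mm), x$config$n_cycles))
  cat(sprintf("cycle convergence %.3g, conservation imbalance %.3g, mean inlet flow %.4f mL/s\n",
              x$meta$convergence, x$meta$conservation, x$meta$mean_inlet_flow_ml_s))
  invisible(x)
}

#' Cycle-to-cycle convergence of the probe area series
#'
#' Maximum relative difference of the probe-vicinity-averaged cross-sectional
#' area between the second and third simulated cardiac cycles, taken over
#' both measurement locations and all time moments of the cycle. Values below
#' 1e-4 (0.01 %) indicate that the start-up ramp transient has died out and
#' the final cycle is representative.
#'
#' @param field A `hemo_field` with at least 3 cycles.
#' @param geom The geometry used for the simulation.
#' @return Dimensionless fraction (multiply by 100 for percent).
#' @export
cycle_convergence <- function(field, geom = field$geometry) {
  if (field$config$n_cycles < 3) stop("at least 3 simulated cycles are required")
  worst <- 0
  for (loc in c("ioa", "eoa")) {
    a2 <- probe_cycle_matrix(field, geom, loc, cycle = 2)
    a3 <- probe_cycle_matrix(field, geom, loc, cycle = 3)
    worst <- max(worst, max(abs(a3 - a2) / a2))
  }
  worst
}

# vicinity-averaged probe area series for one cycle
probe_cycle_matrix <- function(field, geom, location, cycle) {
  x0 <- if (location == "ioa") geom$probe_ioa else geom$probe_eoa
  h <- geom$probe_halfwidth
  cols <- which(field$x_mm >= x0 - h & field$x_mm <= x0 + h)
  rows <- which(field$cycle == cycle)
  rowMeans(field$area_mm2[rows, cols, drop = FALSE])
}

# |inlet - outlet - storage| over the final cycle, relative to throughput
conservation_imbalance <- function(field) {
  spc <- field$config$samples_per_cycle
  dt <- field$config$dt
  rows <- which(field$cycle == field$config$n_cycles)
  r0 <- rows[1] - 1L                       # state at the start of the final cycle
  seg <- c(r0, rows)
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * dt
  v_in <- trap(field$inlet_flow_ml_s[seg])
  v_out <- trap(field$outlet_flow_ml_s[seg])
  dx_mm <- field$x_mm[2] - field$x_mm[1]
  vol <- function(r) sum(field$area_mm2[r, ] * dx_mm) / 1000   # mL
  storage <- vol(rows[length(rows)]) - vol(r0)
  abs(v_in - v_out - storage) / v_in
}
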