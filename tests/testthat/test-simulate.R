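test_that("rigid steady flow reproduces the analytic Poiseuille solution", {
  g <- oa_geometry(compliance = c(ioa = 0, canal = 0, eoa = 0))
  ld <- pressure_load(icp = 0, pio = 0, pe = 0, inlet_amplitude = 0,
                      waveform = "constant")
  f <- simulate_oa(g, ld, sim_config())
  q <- f$meta$mean_inlet_flow_ml_s
  # velocity uniform along the vessel
  final <- f$velocity_cm_s[nrow(f$velocity_cm_s), ]
  expect_lt(diff(range(final)) / mean(final), 1e-6)
  # simulated inter-probe pressure drop equals the closed form within 1%
  dp_sim <- probe(f, g, "ioa")$mean_pressure_mmhg -
    probe(f, g, "eoa")$mean_pressure_mmhg
  expect_equal(dp_sim, poiseuille_pressure_drop(g, q), tolerance = 0.01)
  # pressure is linear in x within each uniform-radius vessel
  p_final <- f$pressure_mmhg[nrow(f$pressure_mmhg), ]
  fit <- lm(p_final ~ f$x_mm)
  expect_lt(max(abs(residuals(fit))), 1e-6)
})

test_that("the volume budget closes over the final cycle", {
  f <- simulate_oa(oa_geometry(), pressure_load(icp = 20, pe = 14), fast_config())
  expect_lt(f$meta$conservation, 1e-3)
})

test_that("three-cycle ramp protocol converges below 0.01% at the default grid point", {
  f <- simulate_oa(oa_geometry(), pressure_load(icp = 20, pe = 14), sim_config())
  expect_lt(f$meta$convergence, 1e-4)
})

test_that("probe averaging honors its contracts", {
  g <- oa_geometry()
  f <- simulate_oa(g, pressure_load(icp = 20, pe = 14), sim_config())
  p_ioa <- probe(f, g, "ioa")
  # 250 time moments for the default configuration
  expect_identical(nrow(p_ioa$samples), 250L)
  # cycle average is exactly the arithmetic mean of the per-moment values
  expect_identical(p_ioa$mean_velocity_cm_s, mean(p_ioa$samples$velocity_cm_s))
  expect_identical(p_ioa$mean_area_mm2, mean(p_ioa$samples$area_mm2))
  # spatially uniform synthetic field: probe returns the field value
  fu <- f
  fu$velocity_cm_s[] <- 7
  expect_equal(unique(probe(fu, g, "ioa")$samples$velocity_cm_s), 7)
})

test_that("cycle_convergence computes the stated ratio and rejects short runs", {
  g <- oa_geometry()
  f <- simulate_oa(g, pressure_load(icp = 10), fast_config())
  # exactly periodic synthetic field -> 0
  fp <- f
  spc <- f$config$samples_per_cycle
  rows2 <- which(f$cycle == 2); rows3 <- which(f$cycle == 3)
  fp$area_mm2[rows3, ] <- fp$area_mm2[rows2, ]
  expect_equal(cycle_convergence(fp, g), 0)
  # cycle 3 area = 1.0001 x cycle 2 area -> 1e-4
  fp$area_mm2[rows3, ] <- 1.0001 * fp$area_mm2[rows2, ]
  expect_equal(cycle_convergence(fp, g), 1e-4, tolerance = 1e-9)
  f2 <- f; f2$config$n_cycles <- 2
  expect_error(cycle_convergence(f2, g), "at least 3")
})

test_that("EOA area decreases and velocity increases with Pe at fixed ICP", {
  g <- oa_geometry()
  cfg <- fast_config()
  probes <- lapply(c(4, 14, 24), function(pe) {
    probe(simulate_oa(g, pressure_load(icp = 20, pe = pe), cfg), g, "eoa")
  })
  areas <- vapply(probes, `[[`, numeric(1), "mean_area_mm2")
  vels <- vapply(probes, `[[`, numeric(1), "mean_velocity_cm_s")
  expect_true(all(diff(areas) < 0))
  expect_true(all(diff(vels) > 0))
})

test_that("symmetric external loading gives equal probe areas", {
  # same compression on both compliant segments, near-zero flow: transmural
  # pressures match, so the probe areas agree within solver tolerance
  g <- oa_geometry()
  ld <- pressure_load(icp = 12, pio = 12, pe = 0, inlet_amplitude = 0,
                      waveform = "constant", outlet_resistance = 1e6)
  f <- simulate_oa(g, ld, fast_config())
  a_i <- probe(f, g, "ioa")$mean_area_mm2
  a_e <- probe(f, g, "eoa")$mean_area_mm2
  expect_equal(a_i, a_e, tolerance = 1e-6)
})

test_that("configuration mismatches are rejected", {
  expect_error(simulate_oa(oa_geometry(), pressure_load(icp = 10, period = 0.8)),
               "cardiac period")
  expect_error(sim_config(n_cycles = 1), "convergence")
  expect_error(sim_config(ramp_cycles = 3), "settled")
})
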