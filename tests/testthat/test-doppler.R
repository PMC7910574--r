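test_that("synthetic intensity is proportional, reproducible and positive", {
  a <- 1.5 + 0.1 * sin(seq(0, 20, by = 0.01))
  expect_equal(synthesize_intensity(a, gain = 3, noise_sd_fraction = 0), 3 * a)
  s1 <- synthesize_intensity(a, 2, 0.1, seed = 7)
  s2 <- synthesize_intensity(a, 2, 0.1, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0))
  expect_error(synthesize_intensity(a, gain = 0), "positive")
  # sample fractional SD of 1e4 draws within 10% of requested
  s <- synthesize_intensity(rep(1, 1e4), 1, 0.08, seed = 11)
  expect_equal(sd(s / 1), 0.08, tolerance = 0.1)
})

test_that("BFF closed-form cases: unity, constant ratio, gain invariance", {
  n <- 3000; fs <- 100
  base <- 2 + 0.4 * sin(2 * pi * seq_len(n) / fs)
  tr_same <- doppler_trace(base, base, fs)
  expect_equal(unique(compute_bff(tr_same)$samples$bff), 0)
  tr_e <- doppler_trace(exp(1) * base, base, fs)
  expect_equal(compute_bff(tr_e)$samples$bff, rep(1, 3), tolerance = 1e-12)
  # common multiplicative gain cancels in the log ratio
  tr_a <- doppler_trace(1.3 * base, 0.9 * base, fs)
  tr_b <- doppler_trace(5 * 1.3 * base, 5 * 0.9 * base, fs)
  expect_equal(compute_bff(tr_a)$samples$bff, compute_bff(tr_b)$samples$bff)
})

test_that("BFF quadrature matches the analytic integral of a sinusoidal log ratio", {
  # ln(Ps_ioa/Ps_eoa) = c + m sin(2 pi t / T): over whole periods the
  # time-normalized integral is exactly c
  fs <- 100; T_w <- 10
  t <- seq(0, T_w - 1 / fs, by = 1 / fs)
  logratio <- 0.35 + 0.5 * sin(2 * pi * t / 2)
  tr <- doppler_trace(exp(logratio), rep(1, length(t)), fs)
  expect_equal(compute_bff(tr, T_w)$samples$bff, 0.35, tolerance = 1e-3)
})

test_that("BFF is antisymmetric under channel exchange", {
  tr <- clean_trace(duration_s = 40, ratio = 1.7)
  sw <- doppler_trace(tr$samples$ps_eoa, tr$samples$ps_ioa, tr$fs_hz)
  expect_equal(compute_bff(sw)$samples$bff, -compute_bff(tr)$samples$bff)
})

test_that("scaling the IOA channel by k shifts every BFF value by ln k", {
  tr <- clean_trace(duration_s = 40)
  k <- 2.5
  up <- doppler_trace(k * tr$samples$ps_ioa, tr$samples$ps_eoa, tr$fs_hz)
  expect_equal(compute_bff(up)$samples$bff,
               compute_bff(tr)$samples$bff + log(k), tolerance = 1e-12)
})

test_that("windows with under half their samples valid are masked, not dropped", {
  tr <- clean_trace(duration_s = 30)
  bad <- tr
  bad$samples$valid[1:600] <- FALSE          # 60% of window 1 invalid
  b <- compute_bff(bad)
  expect_identical(nrow(b$samples), 3L)
  expect_false(b$samples$valid[1])
  expect_true(all(b$samples$valid[2:3]))
  expect_true(is.na(b$samples$bff[1]))
  # non-positive intensity among valid samples is an error
  neg <- tr; neg$samples$ps_ioa[5] <- -1
  expect_error(compute_bff(neg), "positive")
})

test_that("artifact filter leaves clean traces untouched", {
  tr <- clean_trace()
  out <- artifact_filter(tr)
  expect_identical(out$samples$valid, tr$samples$valid)
  expect_identical(out$meta$artifacts_removed, 0L)
})

test_that("an injected spike is masked exactly", {
  tr <- clean_trace()
  i_spike <- 1500L
  tr$samples$ps_ioa[i_spike] <- 20 * median(tr$samples$ps_ioa)
  out <- artifact_filter(tr)
  expect_identical(which(!out$samples$valid), i_spike)
})

test_that("a 3-second dropout is masked in full", {
  tr <- clean_trace()
  drop_idx <- 1001:1300                      # 3 s at 100 Hz
  tr$samples$ps_eoa[drop_idx] <- 1e-4
  out <- artifact_filter(tr)
  expect_true(all(!out$samples$valid[drop_idx]))
  expect_gte(mean(out$samples$valid), 0.85)
})

test_that("moving average smooths with shrinking edge windows", {
  # constant series unchanged
  expect_equal(moving_average(rep(3, 20), 60, dt_s = 10), rep(3, 20))
  # unit step on a 7-point 0.1 Hz fixture: value at the step index is the
  # mean of the (partial or full) window contents
  x <- c(0, 0, 0, 1, 1, 1, 1)
  out <- moving_average(x, 60, dt_s = 10)
  expect_equal(out[4], mean(x))              # full 7-point window
  expect_equal(out[1], mean(x[1:4]))         # edge: partial window
  expect_length(out, length(x))
  expect_error(moving_average(numeric(0), 60, dt_s = 10), "empty")
})

test_that("mean BFF responds monotonically to ICP in monitoring mode", {
  # two simulated runs, Pe = 0: higher ICP compresses the intracranial
  # segment, lowering the IOA/EOA intensity ratio, so mean BFF moves in a
  # consistent direction that the per-subject linear calibration absorbs
  g <- oa_geometry()
  cfg <- fast_config()
  mean_bff_at <- function(icp) {
    f <- simulate_oa(g, pressure_load(icp = icp, pe = 0), cfg)
    a_i <- probe(f, g, "ioa")$samples$area_mm2
    a_e <- probe(f, g, "eoa")$samples$area_mm2
    reps <- ceiling(10 * 250 / length(a_i))
    tr <- doppler_trace(synthesize_intensity(rep(a_i, reps), gain = 2),
                        synthesize_intensity(rep(a_e, reps), gain = 3),
                        fs_hz = 250)
    mean(compute_bff(tr)$samples$bff)
  }
  b10 <- mean_bff_at(10); b20 <- mean_bff_at(20)
  expect_lt(b20, b10)
  # a calibration fitted on (bff, icp) pairs then has a consistent sign
  expect_lt((20 - 10) / (b20 - b10), 0)
})
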