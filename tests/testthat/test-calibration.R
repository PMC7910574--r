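test_that("exact linear data recovers the calibration coefficients to 6 decimals", {
  bff <- seq(0.02, 0.2, length.out = 20)
  m <- fit_calibration(bff, 56.3 * bff + 10.1)
  expect_equal(m$slope, 56.3, tolerance = 1e-8)
  expect_equal(m$intercept, 10.1, tolerance = 1e-8)
  expect_equal(m$residual_sd, 0, tolerance = 1e-8)
})

test_that("two points give the exact interpolating line", {
  m <- fit_calibration(c(0.1, 0.3), c(12, 18))
  expect_equal(m$slope, 30)
  expect_equal(m$intercept, 9)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration(rep(0.1, 5), 1:5), "uncalibratable")
  expect_error(fit_calibration(1:3, 1:2), "equal length")
  expect_error(fit_calibration(0.1, 12), "at least 2")
})

test_that("OLS recovery stays within 3 analytic standard errors across replicates", {
  # truth (a, b) = (109.8, 3.8), Gaussian response noise SD 1 mmHg, n = 60
  set.seed(20250923)
  hits <- vapply(seq_len(500), function(i) {
    bff <- runif(60, 0.02, 0.12)
    icp <- 109.8 * bff + 3.8 + rnorm(60, 0, 1)
    m <- fit_calibration(bff, icp)
    abs(m$slope - 109.8) <= 3 * m$slope_se &&
      abs(m$intercept - 3.8) <= 3 * m$intercept_se
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("apply_calibration is the stated affine map with mask propagation", {
  m <- list(slope = 70.4, intercept = 6.2)
  expect_equal(apply_calibration(m, 0), 6.2)
  expect_equal(apply_calibration(m, 0.05), 9.72)
  b <- structure(list(samples = data.frame(time_s = c(10, 20, 30),
                                           bff = c(0, 0.05, 0.1),
                                           valid = c(TRUE, FALSE, TRUE)),
                      window_s = 10), class = "bff_series")
  out <- apply_calibration(m, b)
  expect_equal(out$icp_noninv_mmhg, c(6.2, 9.72, 13.24))
  expect_identical(out$valid, c(TRUE, FALSE, TRUE))
})

test_that("refitting on noiseless calibrated output is idempotent", {
  bff <- seq(0.01, 0.2, length.out = 30)
  m <- fit_calibration(bff, 218.9 * bff + 4.5)
  m2 <- fit_calibration(bff, apply_calibration(m, bff))
  expect_equal(m2$slope, m$slope)
  expect_equal(m2$intercept, m$intercept)
})

test_that("sessions enforce 10 s pairing and the monitoring duration cap", {
  expect_error(monitoring_session("s", c(0, 10, 25), 1:3, 1:3), "10 s steps")
  expect_error(monitoring_session("s", seq(0, 4000, by = 10),
                                  rep(10, 401), rep(0.1, 401)), "duration")
})

test_that("noiseless monitoring recovers the reference exactly", {
  spec <- default_cohort(3)
  p <- profile_row(spec, 1)
  p$diff_sd <- 0
  session <- generate_session(p, seed = 11)
  res <- monitor_subject(session, calib_points = 30)
  expect_lt(res$monitoring$summary$max_abs_diff, 0.01)
  expect_equal(res$model$slope, p$slope, tolerance = 1e-6)
  # output pair count equals the valid post-calibration BFF count
  expect_identical(res$monitoring$summary$n, p$n_points - 30L)
})

test_that("a noisy subject-1-like profile lands at order 1-2 mmHg max difference", {
  spec <- default_cohort(5)
  session <- generate_session(profile_row(spec, 1), seed = 21)
  res <- monitor_subject(session, calib_points = 30, smooth = TRUE)
  expect_lt(res$monitoring$summary$max_abs_diff, 4)
  expect_gt(res$monitoring$summary$max_abs_diff, 0.2)
})

test_that("affine rescaling of BFF leaves calibrated estimates invariant", {
  spec <- default_cohort(7)
  session <- generate_session(profile_row(spec, 2), seed = 31)
  res1 <- monitor_subject(session, calib_points = 30)
  session2 <- session
  session2$records$bff <- -2.5 * session$records$bff + 0.7
  res2 <- monitor_subject(session2, calib_points = 30)
  expect_equal(res2$monitoring$pairs$icp_noninv_mmhg,
               res1$monitoring$pairs$icp_noninv_mmhg, tolerance = 1e-9)
})

test_that("smoothing both series reduces the difference spread", {
  spec <- default_cohort(9)
  session <- generate_session(profile_row(spec, 4), seed = 41)
  raw <- monitor_subject(session, calib_points = 30, smooth = FALSE)
  sm <- monitor_subject(session, calib_points = 30, smooth = TRUE)
  expect_lt(sm$monitoring$summary$sd_diff, raw$monitoring$summary$sd_diff)
})
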