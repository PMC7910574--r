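test_that("default cohort reproduces the pilot structure", {
  spec <- default_cohort()
  s <- spec$subjects
  expect_identical(sum(s$n_points), 1928L)
  expect_equal(s$slope[1], 56.3)
  expect_equal(s$intercept[1], 10.1)
  expect_true(all(s$slope > 0))
  expect_identical(nrow(s), 6L)
  expect_true(all(s$icp_min < s$icp_max))
})

test_that("cohort specs validate their profiles", {
  s <- default_cohort()$subjects
  s$subject[2] <- 1
  expect_error(cohort_spec(s), "unique")
  s <- default_cohort()$subjects
  s$icp_min[1] <- s$icp_max[1]
  expect_error(cohort_spec(s), "below")
})

test_that("trajectories stay in range, are seeded and strongly autocorrelated", {
  spec <- default_cohort()
  for (i in c(1, 3, 5)) {
    p <- profile_row(spec, i)
    tr <- generate_icp_trajectory(p)
    expect_true(all(tr >= p$icp_min & tr <= p$icp_max))
    expect_identical(tr, generate_icp_trajectory(p))
    expect_length(tr, p$n_points)
  }
  # lag-1 autocorrelation above 0.9 over a full-length session
  p2 <- profile_row(spec, 2)
  tr2 <- generate_icp_trajectory(p2)
  expect_gt(cor(tr2[-1], tr2[-length(tr2)]), 0.9)
})

test_that("sessions pair at exactly 10 s and are reproducible", {
  spec <- default_cohort()
  s <- generate_session(profile_row(spec, 4))
  expect_equal(unique(diff(s$records$time_s)), 10)
  expect_identical(nrow(s$records), 280L)
  s2 <- generate_session(profile_row(spec, 4))
  expect_identical(s$records, s2$records)
})

test_that("the empirical difference SD is governed by the profile diff_sd", {
  # subject-5-like profile (truth 0.64, n = 360): across seeds the sample SD
  # of invasive minus calibrated non-invasive stays inside the wide
  # chi-square-style envelope [0.45, 0.85]
  spec <- default_cohort()
  p <- profile_row(spec, 5)
  sds <- vapply(1:60, function(seed) {
    s <- generate_session(p, seed = seed)
    monitor_subject(s, calib_points = 30)$monitoring$summary$sd_diff
  }, numeric(1))
  expect_gte(mean(sds >= 0.45 & sds <= 0.85), 0.95)
})

test_that("the cohort generator is deterministic in the master seed", {
  c1 <- generate_cohort(default_cohort(17))
  c2 <- generate_cohort(default_cohort(17))
  expect_identical(lapply(c1, `[[`, "records"), lapply(c2, `[[`, "records"))
  expect_length(c1, 6L)
  expect_identical(sum(vapply(c1, function(s) nrow(s$records), integer(1))), 1928L)
  # a different master seed produces different data
  c3 <- generate_cohort(default_cohort(18))
  expect_false(identical(c1[[1]]$records$icp_inv_mmhg,
                         c3[[1]]$records$icp_inv_mmhg))
})

test_that("end-to-end: calibrate, monitor, evaluate recovers the cohort truth", {
  spec <- default_cohort(1)
  ev <- evaluate_cohort(generate_cohort(spec))
  truth <- spec$subjects
  # per-subject coefficients within 3 analytic standard errors of truth
  expect_true(all(abs(ev$per_subject$slope - truth$slope) <=
                    3 * ev$per_subject$slope_se))
  expect_true(all(abs(ev$per_subject$intercept - truth$intercept) <=
                    3 * ev$per_subject$intercept_se))
  # pooled statistics inside the qualitative cohort envelope
  expect_gt(ev$pooled$pooled_mean, -0.5)
  expect_lt(ev$pooled$pooled_mean, 0.5)
  expect_gt(ev$pooled$pooled_sd, 0.6)
  expect_lt(ev$pooled$pooled_sd, 2.0)
  expect_gt(ev$regression$r, 0.9)
})

test_that("pooled statistics stay in the envelope across master seeds", {
  stats <- t(vapply(1:20, function(seed) {
    ev <- evaluate_cohort(generate_cohort(default_cohort(seed)))
    c(ev$pooled$pooled_mean, ev$pooled$pooled_sd)
  }, numeric(2)))
  expect_true(all(stats[, 1] > -0.5 & stats[, 1] < 0.5))
  expect_true(all(stats[, 2] > 0.6 & stats[, 2] < 2.0))
})
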