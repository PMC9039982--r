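# Driving-pressure estimators.

test_that("true driving pressure is the plateau minus total PEEP", {
  expect_equal(dp_true(28, 13), 15)
  expect_equal(dp_true(30, 30), 0)
  expect_error(dp_true(10, 12), ">=")
})

test_that("time-constant intrinsic-PEEP formula matches hand values", {
  expect_equal(as.numeric(peepi_tau(0.5, 1, 0.4, 20, n_tau = 4)), 12)
  expect_equal(as.numeric(peepi_tau(0.5, 1, 0.4, 20, n_tau = 3)), 7)
  # released volume equal to the assumed full exhalation gives zero
  expect_equal(as.numeric(peepi_tau(0.5, 1, 0.5 * 4 * 0.5 * 1, 20,
                                    n_tau = 4)), 0)
  # negative estimates clamp to zero and are flagged
  est <- peepi_tau(0.1, 1, 0.4, 20, n_tau = 3)
  expect_equal(as.numeric(est), 0)
  expect_true(attr(est, "clamped"))
  expect_error(peepi_tau(0.5, 1, 0.4, 20, n_tau = 5), "3 or 4")
})

test_that("driving pressure from intrinsic PEEP subtracts both pressures", {
  expect_equal(dp_from_peepi(30, 5, 10), 15)
  expect_equal(dp_from_peepi(30, 0, 0), 30)
  expect_equal(dp_from_peepi(25, 0, 11), 14)
})

test_that("mono-exponential estimate depends only on the flow ratio", {
  expect_equal(dp_mono(30, 0, 0, 1), 30)
  expect_equal(dp_mono(30, 5, 0.4, 1), 30 - (12 + 5))
  # unit invariance: L/s and L/min give identical results
  expect_equal(dp_mono(30, 5, 0.4, 1.0), dp_mono(30, 5, 24, 60))
  expect_error(dp_mono(30, 5, 1.2, 1.0), "eefr")
  expect_error(dp_mono(30, 5, 0.4, 0), "pefr")
})

test_that("mono-exponential estimate is exact for a linear lung at P_low 0", {
  p <- rc_patient()
  stg <- aprv_settings(p_high = 30, p_low = 0, t_high = 5, t_low = 0.5)
  run <- run_aprv(p, stg, duration = 33, dt = 0.001)
  m <- extract_measurements(run)
  truth <- dp_true(m$p_plat, m$peep_tot)
  est <- dp_mono(30, 0, m$eefr_L_s, m$pefr_L_s)
  expect_equal(est, 30 * (1 - exp(-1)), tolerance = 0.01)
  expect_equal(est, truth, tolerance = 0.02)
})

test_that("VCV switch reproduces the true driving pressure on a linear lung", {
  p <- rc_patient()
  stg <- aprv_settings(p_high = 30, p_low = 5, t_high = 5, t_low = 0.5)
  run <- run_aprv(p, stg, duration = 33, dt = 0.001)
  m <- extract_measurements(run)
  est <- dp_vcv_switch(p, m, rr = 12, dc = 0.4, duration = 120, dt = 0.001)
  # linear statics: P_plat(VCV) - PEEP = VT * E = dp_true
  expect_equal(as.numeric(est), m$v_released / 0.05, tolerance = 0.02)
  expect_equal(as.numeric(est), dp_true(m$p_plat, m$peep_tot),
               tolerance = 0.03)
  mv <- attr(est, "vcv_measurements")
  expect_s3_class(mv, "measurement_set")
})

test_that("dp_report assembles estimates and errors coherently", {
  p <- rc_patient()
  stg <- aprv_settings(p_high = 30, p_low = 0, t_high = 5, t_low = 0.5)
  run <- run_aprv(p, stg, duration = 33, dt = 0.001)
  m <- extract_measurements(run)
  rep <- dp_report(p, m, stg, rr = 12, dc = 0.4, dt = 0.001)
  expect_s3_class(rep, "dp_report")
  expect_equal(rep$err_mono, rep$dp_mono - rep$dp_true)
  expect_equal(rep$err_vcv, rep$dp_vcv - rep$dp_true)
  expect_equal(rep$tau, rep$r_aw * rep$compliance)
  # for the linear fixture tau = 0.5 s
  expect_equal(rep$tau, 0.5, tolerance = 0.03)
})
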