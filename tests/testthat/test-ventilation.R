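# Ventilator programs and measurement extraction.

test_that("APRV mandatory rate follows the cycle time", {
  stg <- aprv_settings(p_high = 30, p_low = 5, t_high = 5, t_low = 0.5)
  expect_equal(mandatory_rate(stg), 60 / 5.5)
  expect_equal(round(mandatory_rate(stg)), 11)
})

test_that("ventilator setting validation rejects impossible programs", {
  expect_error(aprv_settings(p_high = 5, p_low = 10))
  expect_error(aprv_settings(p_high = 30, p_low = -1))
  expect_error(vcv_settings(vt = -0.4, peep = 5, rr = 15))
  expect_error(vcv_settings(vt = 0.4, peep = 5, rr = 15, dc = 1.2))
})

test_that("long releases empty the lung to P_low", {
  p <- rc_patient()  # tau = 0.5 s
  stg <- aprv_settings(p_high = 30, p_low = 2, t_high = 5, t_low = 8)
  run <- run_aprv(p, stg, duration = 80, dt = 0.001)
  m <- extract_measurements(run)
  expect_equal(m$peep_tot, 2, tolerance = 0.02)
})

test_that("truncated release of the RC patient traps pressure as e^-T/tau", {
  p <- rc_patient()
  stg <- aprv_settings(p_high = 30, p_low = 0, t_high = 5, t_low = 0.5)
  run <- run_aprv(p, stg, duration = 33, dt = 0.001)
  m <- extract_measurements(run)
  expect_equal(m$peep_tot, 30 * exp(-1), tolerance = 0.01)
  # measurement identities on the analytic fixture
  expect_equal(m$pefr_L_s, (m$p_plat - 0) / 10, tolerance = 0.01)
  expect_equal(m$eefr_L_s, m$pefr_L_s * exp(-1), tolerance = 0.01)
  expect_equal(m$v_released, 0.05 * (m$p_plat - m$peep_tot),
               tolerance = 0.01)
  expect_equal(m$r_aw, 10, tolerance = 0.01)
  expect_equal(m$compliance, 0.05, tolerance = 0.02)
})

test_that("VCV statics recover compliance on a linear patient", {
  p <- rc_patient(resistance = 10, compliance = 0.05)
  stg <- vcv_settings(vt = 0.4, peep = 5, rr = 12, dc = 0.4)
  run <- run_vcv(p, stg, duration = 60, dt = 0.001)
  m <- extract_measurements(run)
  expect_equal(m$p_plat - m$peep_tot, 0.4 / 0.05, tolerance = 0.02)
  expect_equal(m$compliance, 0.05, tolerance = 0.02)
  expect_gte(m$p_peak, m$p_plat)
  # doubling the tidal volume doubles the static driving pressure
  stg2 <- vcv_settings(vt = 0.8, peep = 5, rr = 12, dc = 0.4)
  m2 <- extract_measurements(run_vcv(p, stg2, duration = 60, dt = 0.001))
  expect_equal(m2$p_plat - m2$peep_tot, 2 * (m$p_plat - m$peep_tot),
               tolerance = 0.02)
  # constant-flow resistive drop identifies the airway resistance
  expect_equal(m$r_aw, 10, tolerance = 0.05)
})

test_that("a nearly resistance-free patient shows no peak-plateau gap", {
  p <- rc_patient(resistance = 0.2, compliance = 0.05)
  stg <- vcv_settings(vt = 0.4, peep = 5, rr = 12, dc = 0.4)
  m <- extract_measurements(run_vcv(p, stg, duration = 60, dt = 5e-5))
  expect_equal(m$p_peak, m$p_plat, tolerance = 0.02)
})

test_that("APRV pressures are ordered P_low <= PEEP_tot <= P_plat <= P_high", {
  p <- ards_patient()
  stg <- aprv_settings(p_high = 30, p_low = 5, fio2 = 0.6)
  m <- extract_measurements(run_aprv(p, stg, duration = 120, dt = 0.002))
  expect_gte(m$peep_tot, 5)
  expect_gte(m$p_plat, m$peep_tot)
  expect_lte(m$p_plat, 30 + 1e-6)
  expect_gte(m$pefr_L_s, m$eefr_L_s)
  expect_gte(m$eefr_L_s, 0)
  expect_equal(m$compliance, 1 / m$elastance)
})

test_that("waveform CSV round-trips with flow in L/min", {
  p <- rc_patient()
  stg <- aprv_settings(p_high = 30, p_low = 0)
  run <- run_aprv(p, stg, duration = 15, dt = 0.002)
  f <- withr::local_tempfile(fileext = ".csv")
  write_waveform(run, f)
  x <- read_waveform(f)
  expect_named(x, c("time_s", "paw_cmH2O", "plung_cmH2O", "flow_L_min",
                    "volume_L", "flow_L_s"))
  expect_equal(x$flow_L_s, run$trace$flow_L_s, tolerance = 1e-8)
  expect_error(read_waveform(withr::local_tempfile(lines = "a,b\n1,2",
                                                   fileext = ".csv")),
               "columns")
})

test_that("incomplete traces are rejected by the extractor", {
  p <- rc_patient()
  stg <- aprv_settings(p_high = 30, p_low = 0)
  run <- run_aprv(p, stg, duration = 15, dt = 0.002)
  run$trace <- run$trace[seq_len(50), ]
  expect_error(extract_measurements(run), "full ventilation cycle")
})
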