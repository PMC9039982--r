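# Mechanics and gas-exchange core.

test_that("compartment PV law is monotone, additive in P_ext, and stiffens", {
  v <- seq(0.005, 0.06, by = 0.001)
  p <- compartment_elastic_pressure(v)
  expect_true(all(diff(p) > 0))
  # additivity in the extrinsic offset
  expect_equal(compartment_elastic_pressure(v, p_ext = 5),
               compartment_elastic_pressure(v) + 5)
  # above the reference volume a stiffer compartment recoils harder
  v_hi <- 0.03
  expect_gt(compartment_elastic_pressure(v_hi, k_stiff = 0.5),
            compartment_elastic_pressure(v_hi, k_stiff = 0))
  expect_error(compartment_elastic_pressure(-0.01), "non-negative")
})

test_that("equilibrium volume inverts the PV law", {
  for (paw in c(0, 5, 15, 30)) {
    v_eq <- compartment_equilibrium_volume(paw, p_ext = 2, k_stiff = 0.2)
    expect_equal(compartment_elastic_pressure(v_eq, p_ext = 2,
                                              k_stiff = 0.2),
                 paw, tolerance = 1e-6)
  }
  # a positive extrinsic pressure above the recoil floor empties the
  # compartment completely
  expect_equal(compartment_equilibrium_volume(0, p_ext = 15), 0)
})

test_that("recruitment transitions follow the threshold rules", {
  closed <- list(is_open = FALSE, volume = 0.0002)
  expect_false(recruitment_update(closed, 29.9, top = 30)$is_open)
  expect_true(recruitment_update(closed, 30.0, top = 30)$is_open)
  # idempotent at constant pressure
  opened <- recruitment_update(closed, 35, top = 30)
  expect_true(recruitment_update(opened, 35, top = 30)$is_open)
  # open compartment closes at <= 1% of reference volume
  low <- list(is_open = TRUE, volume = 0.0002)
  expect_false(recruitment_update(low, 10, top = 30, v_ref = 0.024)$is_open)
  ok <- list(is_open = TRUE, volume = 0.01)
  expect_true(recruitment_update(ok, 10, top = 30, v_ref = 0.024)$is_open)
})

test_that("healthy reference patient relaxes to 2.5 L at zero pressure", {
  frc <- relaxed_lung_volume(healthy_reference_patient())
  expect_equal(frc, 2.5, tolerance = 0.05 / 2.5)
})

test_that("pressure release of a linear compartment matches the RC closed form", {
  p <- rc_patient()  # R = 10, C = 0.05, tau = 0.5 s
  stg <- aprv_settings(p_high = 30, p_low = 0, t_high = 5, t_low = 0.5)
  run <- run_aprv(p, stg, duration = 33, dt = 0.001)
  tr <- run$trace
  t_end <- max(tr$time_s)
  t_r <- t_end - 0.5
  rel <- tr[tr$time_s > t_r + 1e-9 & tr$time_s <= t_end - 1e-9, ]
  p0 <- tr$plung_cmH2O[which.min(abs(tr$time_s - t_r))]
  flow_an <- -(p0 / 10) * exp(-(rel$time_s - t_r) / 0.5)
  expect_lt(max(abs(rel$flow_L_s - flow_an)) / (p0 / 10), 0.01)
  # lung pressure decays with the same time constant
  p_an <- p0 * exp(-(rel$time_s - t_r) / 0.5)
  expect_lt(max(abs(rel$plung_cmH2O - p_an)) / p0, 0.01)
})

test_that("volume is conserved over a breath", {
  p <- ards_patient()
  stg <- aprv_settings(p_high = 30, p_low = 5, fio2 = 0.6)
  run <- run_aprv(p, stg, duration = 60, dt = 0.001)
  tr <- run$trace
  dt <- median(diff(tr$time_s))
  # trapezoidal integral of mouth flow vs change in total lung volume
  dv <- diff(range(0, cumsum(tr$flow_L_s[-1] + tr$flow_L_s[-nrow(tr)]) *
                     dt / 2))
  flow_int <- sum((tr$flow_L_s[-1] + tr$flow_L_s[-nrow(tr)]) / 2) * dt
  vol_change <- tr$volume_L[nrow(tr)] - tr$volume_L[1]
  expect_lt(abs(flow_int - vol_change), 1e-4)
})

test_that("oversized integration steps are rejected with the bound named", {
  p <- rc_patient(resistance = 1, compliance = 0.005)  # tau = 5 ms
  stg <- aprv_settings(p_high = 10, p_low = 0)
  expect_error(simulate_patient(p, stg, duration = 1, dt = 0.05),
               "stability bound")
})

test_that("raising pressure never closes an open compartment", {
  p <- ards_patient()
  stg1 <- aprv_settings(p_high = 20, p_low = 5, fio2 = 0.6)
  stg2 <- aprv_settings(p_high = 35, p_low = 5, fio2 = 0.6)
  r1 <- run_aprv(p, stg1, duration = 60, dt = 0.002)
  r2 <- run_aprv(p, stg2, duration = 60, dt = 0.002)
  expect_gte(max(r2$trace$n_open), max(r1$trace$n_open))
})

test_that("steady-state gas exchange balances metabolic demand", {
  p <- ards_patient()
  stg <- vcv_settings(vt = 0.42, peep = 8, rr = 20, dc = 0.35, fio2 = 0.6)
  run <- run_vcv(p, stg, duration = 90, dt = 0.0025, store_cycles = 4,
                 accel_cycles = 6)
  minutes <- run$window_s / 60
  expect_equal(run$o2_uptake_ml / minutes, p$vo2, tolerance = 0.05)
  expect_equal(run$co2_output_ml / minutes, p$rq * p$vo2, tolerance = 0.05)
})

test_that("blood gas mixing handles shunt limits and Fick consistency", {
  p <- ards_patient()
  # zero shunt, identical compartments: arterial = end-capillary
  bg0 <- blood_gas(pa_o2 = rep(100, 4), pa_co2 = rep(40, 4),
                   weights = c(rep(0.25, 4), 0), p)
  expect_equal(bg0$ca_o2, o2_blood_content(100, p$hb), tolerance = 1e-6)
  # VCO2 = RQ * VO2 at the Fick steady state
  expect_equal(bg0$cv_co2 - bg0$ca_co2, p$rq * p$vo2 / p$cardiac_output)
  # full shunt: arterial equals mixed venous (supplied)
  mv <- list(cv_o2 = o2_blood_content(40, p$hb),
             cv_co2 = co2_blood_content(46))
  bg1 <- blood_gas(pa_o2 = numeric(0), pa_co2 = numeric(0), weights = 1,
                   p, mixed_venous = mv)
  expect_equal(bg1$pao2, 40, tolerance = 0.01)
  expect_error(blood_gas(numeric(0), numeric(0), 1, p), "Fick")
  # more shunt lowers PaO2
  bg_lo <- blood_gas(rep(400, 4), rep(40, 4), c(rep(0.225, 4), 0.1), p)
  bg_hi <- blood_gas(rep(400, 4), rep(40, 4), c(rep(0.2, 4), 0.2), p)
  expect_lt(bg_hi$pao2, bg_lo$pao2)
})

test_that("doubling anatomical shunt lowers simulated PaO2", {
  g <- c(0.30, 6, 4, 27.5, 1, 0.15, 0.4, 17, 5, 60, 10,
         0.8, 225, 120, 1, 100)
  p1 <- decode_virtual_patient(g, "distribution")
  g[15] <- 2
  p2 <- decode_virtual_patient(g, "distribution")
  tg <- list(VT = 0.42, FiO2 = 0.6, PEEP = 8, RR = 20, DC = 0.35)
  expect_lt(baseline_outputs(p2, tg)[["PaO2"]],
            baseline_outputs(p1, tg)[["PaO2"]])
})

test_that("patient files round-trip", {
  p <- ards_patient()
  f <- withr::local_tempfile(fileext = ".txt")
  write_patient(p, f)
  q <- read_patient(f)
  expect_equal(q$p_ext, p$p_ext, tolerance = 1e-8)
  expect_equal(q$top, p$top, tolerance = 1e-8)
  expect_equal(q$vd, p$vd, tolerance = 1e-8)
  expect_equal(q$hb, p$hb)
})

test_that("patient parameter validation enforces the allowed ranges", {
  expect_error(virtual_patient(p_ext = -60, k_stiff = 0, top = 30),
               "p_ext")
  expect_error(virtual_patient(p_ext = 0, k_stiff = 0, top = 300), "top")
  expect_error(virtual_patient(p_ext = 0, k_stiff = 0, top = 30, hb = 50),
               "hb")
})
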