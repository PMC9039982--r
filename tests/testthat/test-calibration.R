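# Calibration cost, encodings and the genetic algorithm.

test_that("calibration cost is the root sum of squared relative errors", {
  y <- c(PaO2 = 100, PaCO2 = 40, PeCO2 = 35, PIP = 30, Pplat = 25,
         TOPmean = 30, Vfrc = 2000)
  expect_equal(calibration_cost(y, y), 0)
  y1 <- y; y1["PaO2"] <- 110
  expect_equal(calibration_cost(y1, y), 0.1)
  y2 <- y; y2["PaO2"] <- 130; y2["PaCO2"] <- 24
  expect_equal(calibration_cost(y2, y), sqrt(0.09 + 0.16))
  y0 <- y; y0["Vfrc"] <- 0
  expect_error(calibration_cost(y, y0), "positive")
})

test_that("decoded patients respect the parameter bounds", {
  bd <- patient_bounds()
  bounds <- aprvdp:::.gene_bounds("distribution", FALSE)
  set.seed(42)
  for (k in 1:25) {
    g <- runif(nrow(bounds), bounds[, 1], bounds[, 2])
    p <- decode_virtual_patient(g, "distribution")
    expect_length(p$p_ext, 100)
    expect_true(all(p$p_ext >= bd$p_ext[1] & p$p_ext <= bd$p_ext[2]))
    expect_true(all(p$k_stiff >= bd$k_stiff[1] & p$k_stiff <= bd$k_stiff[2]))
    expect_true(all(p$top >= bd$top[1] & p$top <= bd$top[2]))
  }
  # full encoding clips out-of-range compartment genes
  g_full <- c(rep(-100, 100), rep(5, 100), rep(300, 100),
              0.8, 225, 120, 1.5, 100)
  pf <- decode_virtual_patient(g_full, "full")
  expect_true(all(pf$p_ext == bd$p_ext[1]))
  expect_true(all(pf$k_stiff == bd$k_stiff[2]))
  expect_true(all(pf$top == bd$top[2]))
  # decode is deterministic
  g <- runif(nrow(bounds), bounds[, 1], bounds[, 2])
  expect_identical(decode_virtual_patient(g, "distribution"),
                   decode_virtual_patient(g, "distribution"))
})

test_that("simulated outputs are invariant to compartment permutation", {
  p <- ards_patient()
  set.seed(7)
  perm <- sample.int(100)
  q <- p
  q$p_ext <- p$p_ext[perm]; q$k_stiff <- p$k_stiff[perm]
  q$top <- p$top[perm]; q$r_b <- p$r_b[perm]; q$r_b_insp <- p$r_b_insp[perm]
  tg <- list(VT = 0.42, FiO2 = 0.6, PEEP = 8, RR = 20, DC = 0.35)
  expect_equal(baseline_outputs(p, tg), baseline_outputs(q, tg),
               tolerance = 1e-10)
})

test_that("the GA improves monotonically and is seed-deterministic", {
  p <- ards_patient()
  targets <- targets_from_patient(p, vt = 0.42, fio2 = 0.6, peep = 8,
                                  rr = 20, dc = 0.35)
  ga <- ga_control(pop_size = 8, generations = 4)
  cr1 <- calibrate_patient(targets, ga = ga, seed = 5, polish_iter = 0)
  cr2 <- calibrate_patient(targets, ga = ga, seed = 5, polish_iter = 0)
  expect_identical(cr1$genes, cr2$genes)
  expect_identical(cr1$J, cr2$J)
  # best-of-generation cost never increases (elitism)
  expect_true(all(diff(cr1$history) <= 1e-12))
  expect_equal(cr1$model_outputs[["TOPmean"]], mean(cr1$patient$top))
})

test_that("targets lacking RR/DC are calibrated with rate genes", {
  p <- ards_patient()
  targets <- targets_from_patient(p, vt = 0.42, fio2 = 0.6, peep = 8,
                                  rr = 20, dc = 0.35)
  targets$RR <- NULL; targets$DC <- NULL
  cr <- calibrate_patient(targets, ga = ga_control(pop_size = 6,
                                                   generations = 2),
                          seed = 3, polish_iter = 0)
  expect_true(all(c("rr", "dc") %in% names(cr$genes)))
  expect_gte(attr(cr$patient, "rr"), 10)
  expect_lte(attr(cr$patient, "dc"), 0.5)
})

test_that("invalid targets are rejected", {
  expect_error(calibrate_patient(list(PaO2 = 100)), "positive")
})
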