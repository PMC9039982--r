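# Synthetic cohort generation.

test_that("largest-remainder apportionment matches hand results", {
  expect_equal(largest_remainder(90, c(0.26, 0.61, 0.13)), c(23L, 55L, 12L))
  expect_equal(sum(largest_remainder(7, c(1, 1, 1) / 3)), 7L)
  expect_equal(largest_remainder(10, c(0.5, 0.5)), c(5L, 5L))
})

test_that("cohort specification validates its inputs", {
  expect_error(cohort_spec(severity_mix = c(severe = 0.5, moderate = 0.5,
                                            mild = 0.5)), "sum to 1")
  expect_error(cohort_spec(n_patients = 0), ">= 1")
})

test_that("berlin severity bands classify by P/F ratio", {
  expect_equal(berlin_severity(c(80, 100, 150, 200, 250)),
               c("severe", "severe", "moderate", "moderate", "mild"))
})

test_that("generated cohorts are deterministic, in-band and calibratable-shaped", {
  spec <- cohort_spec(n_patients = 15, seed = 3)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_equal(coh1, coh2)
  expect_equal(nrow(coh1), 15)
  # severity labels agree with the recorded P/F ratios
  expect_equal(berlin_severity(coh1$PF), coh1$severity)
  counts <- largest_remainder(15, spec$severity_mix)
  expect_equal(as.vector(table(factor(coh1$severity,
                                      c("severe", "moderate", "mild")))),
               counts)
  # all calibration targets strictly positive; tidal volume 6 mL/kg
  tg <- c("PaO2", "PaCO2", "PeCO2", "PIP", "Pplat", "TOPmean", "Vfrc")
  expect_true(all(as.matrix(coh1[, tg]) > 0))
  expect_true(all(coh1$VT == 0.42))
  expect_true(all(coh1$TOPmean == 30))
  expect_true(all(coh1$PF >= 60 & coh1$PF <= 300))
  expect_true(all(coh1$Vfrc > 1000 & coh1$Vfrc < 3000))
  expect_true(all(coh1$PeCO2 < coh1$PaCO2))
})

test_that("cohort targets CSV round-trips", {
  coh <- generate_cohort(cohort_spec(n_patients = 4, seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f)
  x <- read_cohort(f)
  expect_equal(x$PaO2, coh$PaO2, tolerance = 1e-8)
  expect_s3_class(x, "cohort_targets")
  expect_error(read_cohort(withr::local_tempfile(lines = "a,b\n1,2")),
               "columns")
})

test_that("the FiO2/PEEP ladder is monotone", {
  fi <- seq(0.4, 1.0, by = 0.05)
  pe <- aprvdp:::.peep_for_fio2(fi)
  expect_true(all(diff(pe) >= 0))
  expect_equal(aprvdp:::.peep_for_fio2(0.4), 5)
})
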