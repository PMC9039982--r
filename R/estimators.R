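# Bedside estimators of the ventilator driving pressure during APRV.

#' True driving pressure from lung pressure waveforms
#'
#' `dP = P_plat - PEEP_tot`, with both read directly from the simulated
#' lung pressure waveform.
#'
#' @param p_plat plateau (maximum lung) pressure, cmH2O.
#' @param peep_tot total end-expiratory lung pressure, cmH2O.
#' @return Driving pressure (cmH2O).
#' @export
dp_true <- function(p_plat, peep_tot) {
  if (any(p_plat < peep_tot))
    stop("'p_plat' must be >= 'peep_tot'")
  p_plat - peep_tot
}

#' Intrinsic PEEP from the expiratory time-constant formula
#'
#' Under the assumption that full expiration (zero expiratory flow) takes
#' `n_tau` expiratory time constants, the intrinsic PEEP remaining at the
#' end of a truncated release is
#' `PEEP_i = (0.5 * n_tau * tau * PEFR - V_released) * elastance`.
#' Negative estimates are clamped to zero (with attribute `clamped`),
#' since negative intrinsic PEEP is unphysical.
#'
#' @param tau expiratory time constant, resistance times static
#'   compliance (s).
#' @param pefr peak expiratory flow rate (L/s).
#' @param v_released exhaled volume during the release (L).
#' @param elastance respiratory elastance (cmH2O/L).
#' @param n_tau assumed number of time constants to full expiration, 3
#'   or 4.
#' @return Estimated intrinsic PEEP (cmH2O).
#' @export
peepi_tau <- function(tau, pefr, v_released, elastance, n_tau = 4) {
  if (!n_tau %in% c(3, 4)) stop("'n_tau' must be 3 or 4")
  stopifnot(tau > 0, pefr > 0, v_released >= 0, elastance > 0)
  est <- (0.5 * (n_tau * tau * pefr) - v_released) * elastance
  clamped <- est < 0
  structure(pmax(est, 0), clamped = clamped)
}

#' Driving pressure given an intrinsic-PEEP estimate
#'
#' `dP = P_high - (PEEP_i + P_low)`.
#'
#' @param p_high,p_low set APRV pressures (cmH2O).
#' @param peepi estimated intrinsic PEEP (cmH2O).
#' @return Estimated driving pressure (cmH2O).
#' @export
dp_from_peepi <- function(p_high, p_low, peepi) {
  stopifnot(is.finite(p_high), is.finite(p_low), is.finite(peepi))
  p_high - (peepi + p_low)
}

#' Mono-exponential driving-pressure estimate
#'
#' Assuming flow, volume and pressure all decay mono-exponentially during
#' the release, the end-to-peak expiratory flow ratio estimates the
#' fraction of `P_high` remaining at end expiration:
#' `dP = P_high - ((EEFR/PEFR) * P_high + P_low)`.  Only the flow ratio
#' enters, so any consistent flow unit may be used.
#'
#' @param p_high,p_low set APRV pressures (cmH2O).
#' @param eefr,pefr end- and peak expiratory flow magnitudes (same units).
#' @return Estimated driving pressure (cmH2O).
#' @export
dp_mono <- function(p_high, p_low, eefr, pefr) {
  if (pefr <= 0) stop("'pefr' must be positive")
  if (eefr < 0 || eefr > pefr)
    stop("'eefr' must lie in [0, pefr]")
  p_high - ((eefr / pefr) * p_high + p_low)
}

#' Driving-pressure estimate by switching to volume-controlled ventilation
#'
#' Re-ventilates the patient under VCV for five minutes with the tidal
#' volume set to the APRV released volume and PEEP set to the measured
#' total end-expiratory pressure, then reports
#' `P_plat(VCV) - PEEP_set`, i.e. assuming the monitoring PEEP equals the
#' true total end-expiratory pressure.
#'
#' @param patient a [virtual_patient()].
#' @param aprv_measurements a `measurement_set` from a steady-state APRV
#'   run.
#' @param fio2 inspired O2 fraction for the VCV period.
#' @param rr,dc respiratory rate (breaths/min) and duty cycle retained
#'   from the patient's conventional ventilation.
#' @param duration,dt simulation length (s) and step (s).
#' @return Estimated driving pressure (cmH2O), with the VCV
#'   `measurement_set` attached as attribute `vcv_measurements`.
#' @export
dp_vcv_switch <- function(patient, aprv_measurements, fio2 = NULL,
                          rr = 16, dc = 0.33, duration = 300, dt = 0.002) {
  m <- aprv_measurements
  if (is.null(fio2)) fio2 <- m$fio2
  stg <- vcv_settings(vt = m$v_released, peep = m$peep_tot, rr = rr,
                      dc = dc, fio2 = fio2)
  run <- run_vcv(patient, stg, duration = duration, dt = dt)
  mv <- extract_measurements(run)
  structure(mv$p_plat - m$peep_tot, vcv_measurements = mv)
}

#' Full driving-pressure report for one patient at one APRV setting
#'
#' Computes the true driving pressure and all four bedside estimates
#' (mono-exponential, 4-tau, 3-tau, VCV switch) from an APRV measurement
#' set, together with their errors (estimate minus truth).  The expiratory
#' time constant is taken from the same measurement set as
#' `tau = R_aw * C` with the airway resistance and static compliance
#' definitions of [extract_measurements()].
#'
#' @param patient a [virtual_patient()].
#' @param measurements a `measurement_set` from a steady-state APRV run.
#' @param settings the `aprv_settings()` that produced the measurements.
#' @param rr,dc conventional-ventilation rate and duty cycle used for the
#'   VCV switch.
#' @param vcv whether to run the (comparatively slow) VCV-switch estimate.
#' @param dt integration step for the VCV switch (s).
#' @return A one-row data.frame of class `dp_report`: `dp_true`,
#'   `dp_mono`, `dp_tau4`, `dp_tau3`, `dp_vcv` and `err_*` columns
#'   (cmH2O), plus the released volume and mechanics used.
#' @export
dp_report <- function(patient, measurements, settings, rr = 16, dc = 0.33,
                      vcv = TRUE, dt = 0.002) {
  m <- measurements
  truth <- dp_true(m$p_plat, m$peep_tot)
  est_mono <- dp_mono(settings$p_high, settings$p_low, m$eefr_L_s,
                      m$pefr_L_s)
  tau <- m$r_aw * m$compliance
  pi4 <- peepi_tau(tau, m$pefr_L_s, m$v_released, m$elastance, n_tau = 4)
  pi3 <- peepi_tau(tau, m$pefr_L_s, m$v_released, m$elastance, n_tau = 3)
  est_tau4 <- dp_from_peepi(settings$p_high, settings$p_low, as.numeric(pi4))
  est_tau3 <- dp_from_peepi(settings$p_high, settings$p_low, as.numeric(pi3))
  est_vcv <- if (vcv)
    as.numeric(dp_vcv_switch(patient, m, rr = rr, dc = dc, dt = dt))
  else NA_real_
  out <- data.frame(
    dp_true = truth, dp_mono = est_mono, dp_tau4 = est_tau4,
    dp_tau3 = est_tau3, dp_vcv = est_vcv,
    err_mono = est_mono - truth, err_tau4 = est_tau4 - truth,
    err_tau3 = est_tau3 - truth, err_vcv = est_vcv - truth,
    v_released = m$v_released, tau = tau, r_aw = m$r_aw,
    compliance = m$compliance, peep_tot = m$peep_tot, p_plat = m$p_plat)
  class(out) <- c("dp_report", class(out))
  out
}
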