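# Ventilator programs and waveform measurement extraction.

#' Ventilator programs
#'
#' `aprv_settings` describes airway pressure release ventilation: the
#' airway opening is held at `p_high` for `t_high` seconds, then released
#' to `p_low` for `t_low` seconds.  `vcv_settings` describes
#' volume-controlled ventilation: a constant-flow inspiration delivering
#' `vt` litres over the first `flow_frac` of the inspiratory time, an
#' end-inspiratory hold for the remainder, then passive expiration against
#' `peep`.
#'
#' @param p_high,p_low APRV pressure levels (cmH2O), `p_high > p_low >= 0`.
#' @param t_high,t_low APRV phase durations (s).
#' @param vt tidal volume (L).
#' @param peep set expiratory pressure (cmH2O).
#' @param rr respiratory rate (breaths/min).
#' @param dc duty cycle (inspiratory fraction of the cycle, 0-1).
#' @param flow_frac fraction of the inspiratory time spent delivering flow
#'   (the rest is an inspiratory hold for reading plateau pressure).
#' @param fio2 inspired oxygen fraction.
#' @return A `vent_program` list.
#' @export
aprv_settings <- function(p_high, p_low, t_high = 5, t_low = 0.5,
                          fio2 = 0.21) {
  stopifnot(p_high > p_low, p_low >= 0, t_high > 0, t_low > 0,
            fio2 > 0, fio2 <= 1)
  structure(list(mode = "aprv", p_high = p_high, p_low = p_low,
                 t_high = t_high, t_low = t_low, fio2 = fio2,
                 t_cycle = t_high + t_low),
            class = "vent_program")
}

#' @rdname aprv_settings
#' @export
vcv_settings <- function(vt, peep, rr, dc = 0.33, flow_frac = 0.7,
                         fio2 = 0.21) {
  stopifnot(vt > 0, rr > 0, dc > 0, dc < 1, peep >= 0,
            flow_frac > 0, flow_frac <= 1)
  structure(list(mode = "vcv", vt = vt, peep = peep, rr = rr, dc = dc,
                 flow_frac = flow_frac, fio2 = fio2, t_cycle = 60 / rr),
            class = "vent_program")
}

.vent_for_cpp <- function(v) {
  if (v$mode == "aprv")
    list(mode = 1L, p_high = v$p_high, p_low = v$p_low, t_high = v$t_high,
         t_low = v$t_low, fio2 = v$fio2)
  else
    list(mode = 2L, vt = v$vt, peep = v$peep, rr = v$rr, dc = v$dc,
         flow_frac = v$flow_frac, fio2 = v$fio2)
}

#' Mandatory breath rate of an APRV program
#'
#' @param settings an APRV `vent_program`.
#' @return Breaths per minute, `60 / (t_high + t_low)`.
#' @export
mandatory_rate <- function(settings) {
  stopifnot(settings$mode == "aprv")
  60 / (settings$t_high + settings$t_low)
}

#' Ventilate a virtual patient
#'
#' `run_aprv` and `run_vcv` simulate a patient under the given program
#' long enough to reach cyclic steady state, store the final cycles of the
#' waveforms, and attach a steady-state flag (total end-expiratory lung
#' pressure of the last two stored cycles within 0.1 cmH2O).  The slow
#' gas-exchange washin is accelerated for all but the final cycles; the
#' mechanics always run in real time.
#'
#' @param patient a [virtual_patient()].
#' @param settings a `vent_program` of the matching mode.
#' @param duration total simulated time (s); rounded up to whole cycles.
#' @param dt integration step (s).
#' @param store_cycles number of final cycles kept in the trace.
#' @param gas_accel,accel_cycles gas acceleration factor and the number of
#'   final cycles simulated in real time.
#' @param ramp_breaths VCV soft start: breaths over which the tidal
#'   volume ramps up from the relaxed initial state, avoiding a spurious
#'   first-breath recruitment transient.
#' @param init optional initial state (see [simulate_patient()]).
#' @return A `lung_run` (see [simulate_patient()]) whose trace covers the
#'   final `store_cycles` cycles, with attribute `steady` on the trace.
#' @export
run_aprv <- function(patient, settings, duration = 1800, dt = 0.002,
                     store_cycles = 2, gas_accel = 10, accel_cycles = 4,
                     init = NULL) {
  stopifnot(settings$mode == "aprv")
  .run_cyclic(patient, settings, duration, dt, store_cycles, gas_accel,
              accel_cycles, init, ramp_breaths = 0L)
}

#' @rdname run_aprv
#' @export
run_vcv <- function(patient, settings, duration = 300, dt = 0.002,
                    store_cycles = 2, gas_accel = 10, accel_cycles = 4,
                    ramp_breaths = 6L, init = NULL) {
  stopifnot(settings$mode == "vcv")
  .run_cyclic(patient, settings, duration, dt, store_cycles, gas_accel,
              accel_cycles, init, ramp_breaths = ramp_breaths)
}

.run_cyclic <- function(patient, settings, duration, dt, store_cycles,
                        gas_accel, accel_cycles, init, ramp_breaths = 0L) {
  tc <- settings$t_cycle
  n_cycles <- max(ceiling(duration / tc), store_cycles + 1)
  duration <- n_cycles * tc
  # snap the step onto the cycle grid so phase boundaries fall on samples
  dt <- tc / round(tc / dt)
  store_from <- duration - (store_cycles + 1) * tc  # one extra for steady check
  run <- simulate_patient(
    patient, settings, duration = duration, dt = dt,
    store_from = store_from, store_every = 1L,
    gas_accel = gas_accel,
    accel_until = max(0, duration - accel_cycles * tc),
    ramp_breaths = ramp_breaths, init = init)
  tr <- run$trace
  # steady-state check on end-expiratory lung pressure of consecutive cycles
  ends <- duration - tc * seq(store_cycles, 0)
  peeps <- vapply(ends[-1], function(te) {
    tr$plung_cmH2O[which.min(abs(tr$time_s - (te - dt)))]
  }, numeric(1))
  steady <- all(abs(diff(peeps)) < 0.1)
  if (!steady)
    warning("trace did not reach cyclic steady state within the duration")
  run$trace <- tr[tr$time_s >= duration - store_cycles * tc - 1e-9, ]
  attr(run$trace, "steady") <- steady
  run$steady <- steady
  run
}

#' Extract bedside measurements from a simulated trace
#'
#' Computes, over the final complete cycle of a `lung_run`, the quantities
#' recorded for every simulated patient: plateau pressure (maximum of the
#' lung pressure waveform), peak pressure (maximum of the ventilator
#' pressure waveform), total end-expiratory pressure (lung pressure at end
#' expiration), released/tidal volume, peak and end-expiratory flow rates
#' (expiratory magnitudes), functional residual capacity (minimum lung
#' volume), the PaO2/FiO2 ratio, airway resistance, and static compliance
#' and elastance.
#'
#' Compliance is reported as volume per pressure
#' (`C = V_t / (P_plat - PEEP_tot)`, L/cmH2O) and elastance as its inverse.
#' Airway resistance is taken from the expiratory limb,
#' `R = (P_plat - PEEP_tot) / (PEFR - EEFR)`, which equals the true
#' resistance for a mono-exponential release; for volume-controlled traces
#' the constant-flow resistive drop `(P_peak - P_plat) / flow` is used.
#'
#' @param run a `lung_run` from [run_aprv()] or [run_vcv()].
#' @return A `measurement_set` list; pressures in cmH2O, flows reported in
#'   both L/s (`*_L_s`) and L/min (`*_L_min`), volumes in L (`v_frc_ml` in
#'   mL), resistance in cmH2O/(L/s) and cmH2O/(L/min).
#' @export
extract_measurements <- function(run) {
  tr <- run$trace
  stg <- run$vent
  tc <- stg$t_cycle
  t_end <- max(tr$time_s)
  cyc <- tr[tr$time_s > t_end - tc + 1e-9, ]
  span <- max(tr$time_s) - min(tr$time_s)
  if (nrow(cyc) < 10 || span < tc - 2 * median(diff(tr$time_s)) - 1e-9)
    stop("trace does not contain a full ventilation cycle")

  p_plat <- max(cyc$plung_cmH2O)
  p_peak <- max(cyc$paw_cmH2O)
  spacing <- median(diff(cyc$time_s))
  idx <- as.integer(round(cyc$time_s / spacing))
  steps_pc <- as.integer(round(tc / spacing))
  phase_i <- idx %% steps_pc
  t_insp <- if (stg$mode == "aprv") stg$t_high else stg$dc * tc
  exp_phase <- phase_i >= round(t_insp / spacing) & phase_i > 0
  expir <- cyc[exp_phase, ]
  peep_tot <- expir$plung_cmH2O[nrow(expir)]
  v_released <- expir$volume_L[1] - expir$volume_L[nrow(expir)]
  pefr <- max(-expir$flow_L_s, 0)
  eefr <- max(-expir$flow_L_s[nrow(expir)], 0)
  v_frc <- min(cyc$volume_L)
  pao2 <- mean(cyc$pao2_mmHg)
  paco2 <- mean(cyc$paco2_mmHg)
  petco2 <- cyc$petco2_mmHg[nrow(cyc)]
  vt <- if (stg$mode == "vcv") stg$vt else v_released
  dp <- p_plat - peep_tot
  compliance <- if (dp > 1e-9) vt / dp else NA_real_
  r_aw <- if (stg$mode == "vcv") {
    insp <- cyc[!exp_phase & cyc$flow_L_s > 1e-6, ]
    if (nrow(insp)) (p_peak - p_plat) / max(insp$flow_L_s) else NA_real_
  } else {
    if (pefr - eefr > 1e-9) dp / (pefr - eefr) else NA_real_
  }
  structure(list(
    p_plat = p_plat, p_peak = p_peak, pip = p_peak, peep_tot = peep_tot,
    v_released = v_released, v_t = vt,
    pefr_L_s = pefr, pefr_L_min = pefr * 60,
    eefr_L_s = eefr, eefr_L_min = eefr * 60,
    v_frc_ml = v_frc * 1000,
    pao2 = pao2, paco2 = paco2, petco2 = petco2,
    pf_ratio = pao2 / stg$fio2,
    r_aw = r_aw, r_aw_L_min = if (is.na(r_aw)) NA_real_ else r_aw / 60,
    compliance = compliance,
    elastance = if (is.na(compliance)) NA_real_ else 1 / compliance,
    fio2 = stg$fio2, mode = stg$mode,
    steady = isTRUE(run$steady)
  ), class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> (%s)\n", x$mode))
  cat(sprintf("  P_plat %.1f  P_peak %.1f  PEEP_tot %.1f cmH2O  (dP %.1f)\n",
              x$p_plat, x$p_peak, x$peep_tot, x$p_plat - x$peep_tot))
  cat(sprintf("  V_t %.0f mL  PEFR %.0f  EEFR %.0f L/min  V_frc %.0f mL\n",
              x$v_t * 1000, x$pefr_L_min, x$eefr_L_min, x$v_frc_ml))
  cat(sprintf("  PaO2 %.0f  PaCO2 %.0f  Pe'CO2 %.0f mmHg  P/F %.0f\n",
              x$pao2, x$paco2, x$petco2, x$pf_ratio))
  cat(sprintf("  R %.1f cmH2O/(L/s)  C %.0f mL/cmH2O\n",
              x$r_aw, x$compliance * 1000))
  invisible(x)
}

#' Write / read a waveform trace CSV
#'
#' Columns `time_s, paw_cmH2O, plung_cmH2O, flow_L_min, volume_L` with a
#' mandatory header; flow is written in L/min at the file interface.
#'
#' @param run a `lung_run` (or a data.frame with the trace columns).
#' @param path output file.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns a data.frame with flow converted back to L/s.
#' @export
write_waveform <- function(run, path) {
  tr <- if (inherits(run, "lung_run")) run$trace else run
  out <- data.frame(time_s = tr$time_s, paw_cmH2O = tr$paw_cmH2O,
                    plung_cmH2O = tr$plung_cmH2O,
                    flow_L_min = tr$flow_L_s * 60,
                    volume_L = tr$volume_L)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  x <- read.csv(path)
  need <- c("time_s", "paw_cmH2O", "plung_cmH2O", "flow_L_min", "volume_L")
  if (!all(need %in% names(x)))
    stop("waveform CSV must have columns: ", paste(need, collapse = ", "))
  x$flow_L_s <- x$flow_L_min / 60
  x
}
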