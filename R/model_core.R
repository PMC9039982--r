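# Core mechanics and gas-exchange operations.

#' Elastic recoil pressure of an alveolar compartment
#'
#' The compartment pressure-volume law is
#' `P_el(v) = P_ext + a * (exp(b * exp(k_stiff) * (v/v_ref - 1)) - 1)`,
#' an exponential recoil curve that rests at the reference volume `v_ref`
#' when the applied pressure equals `P_ext`.  Recoil is strictly
#' increasing in volume, additive in `P_ext`, and (above the reference
#' volume) increasing in `k_stiff`.
#'
#' @param volume gas volume (L), scalar or vector.
#' @param p_ext extrinsic pressure offset (cmH2O).
#' @param k_stiff dimensionless stiffness index.
#' @param v_ref reference volume (L).
#' @return Recoil pressure (cmH2O).
#' @export
compartment_elastic_pressure <- function(volume, p_ext = 0, k_stiff = 0,
                                         v_ref = 0.024) {
  if (any(volume < 0)) stop("'volume' must be non-negative")
  a <- .aprvdp_const$pv_a; b <- .aprvdp_const$pv_b
  p_ext + a * (exp(b * exp(k_stiff) * (volume / v_ref - 1)) - 1)
}

#' Zero-flow equilibrium volume of a compartment
#'
#' Inverts the pressure-volume law: the volume at which recoil equals the
#' applied pressure.  Returns 0 when the compartment cannot hold gas at
#' that pressure (its recoil at zero volume already exceeds it).
#'
#' @inheritParams compartment_elastic_pressure
#' @param paw applied (airway) pressure, cmH2O.
#' @return Equilibrium volume (L).
#' @export
compartment_equilibrium_volume <- function(paw, p_ext = 0, k_stiff = 0,
                                           v_ref = 0.024) {
  n <- max(length(p_ext), length(k_stiff))
  .cpp_equilibrium_volume(paw, rep_len(p_ext, n), rep_len(k_stiff, n),
                          v_ref, .aprvdp_const$pv_a, .aprvdp_const$pv_b,
                          FALSE, 0)
}

#' Recruitment state update for one compartment
#'
#' A closed compartment opens when the proximal (bronchiolar inlet)
#' pressure reaches its threshold opening pressure; an open compartment
#' closes when its volume has fallen to 1% or less of its reference
#' volume.  Both transitions are idempotent at constant pressure.
#'
#' @param state list with elements `is_open` (logical) and `volume` (L).
#' @param proximal_pressure pressure at the compartment inlet (cmH2O).
#' @param top threshold opening pressure (cmH2O).
#' @param v_ref reference volume (L).
#' @return The updated state list.
#' @export
recruitment_update <- function(state, proximal_pressure, top,
                               v_ref = 0.024) {
  if (!state$is_open && proximal_pressure >= top) {
    state$is_open <- TRUE
  } else if (state$is_open && state$volume <= .aprvdp_const$u_close * v_ref &&
             proximal_pressure < top) {
    # below both the volume threshold and the opening threshold: collapse
    state$is_open <- FALSE
  }
  state
}

# stability guard for the explicit fixed-step update: dt must stay well
# below the shortest mechanical time constant R_b * C_local
.dt_stability_bound <- function(patient) {
  if (patient$linear) {
    tau_min <- min(patient$r_b * patient$c_lin)
  } else {
    # stiffest local compliance over the plausible pressure range
    p_span <- 100
    c_min <- patient$v_ref /
      (patient$pv_b * exp(pmin(patient$k_stiff, 1)) * (p_span + patient$pv_a))
    tau_min <- min(patient$r_b * c_min)
  }
  0.5 * tau_min
}

#' Advance the lung model under a ventilator program
#'
#' Runs the compiled fixed-step core: per-step algebraic solution of the
#' flow distribution among open compartments behind the shared central
#' airway, threshold-opening recruitment, plug-flow gas convection through
#' the series dead space, alveolar-capillary exchange with shunt mixing,
#' and a relaxing mixed-venous pool.  Gas volume is conserved exactly by
#' construction of the flow solve.
#'
#' @param patient a [virtual_patient()].
#' @param vent a ventilator program from [aprv_settings()] or
#'   [vcv_settings()].
#' @param duration simulated time (s).
#' @param dt integration step (s); an error names the stability bound when
#'   `dt` is too large.
#' @param store_from store waveform samples from this time on (s).
#' @param store_every store every `store_every`-th step.
#' @param gas_accel acceleration factor applied to the alveolar gas and
#'   mixed-venous stores before `accel_until`; shortens the washin
#'   transient without moving the cyclic balance point.
#' @param accel_until time (s) at which gas dynamics return to real time.
#' @param ramp_breaths number of initial breaths over which a
#'   volume-controlled program ramps up to the set tidal volume (soft
#'   start; ignored for pressure-cycled programs).
#' @param init optional final state of a previous run to continue from.
#' @return A list with `trace` (data.frame: `time_s`, `paw_cmH2O`,
#'   `plung_cmH2O`, `flow_L_s`, `volume_L`, `pao2_mmHg`, `paco2_mmHg`,
#'   `petco2_mmHg`, `n_open`), `state`, and O2 uptake / CO2 output (mL)
#'   integrated over the stored window.
#' @export
simulate_patient <- function(patient, vent, duration, dt = 0.001,
                             store_from = 0, store_every = 1L,
                             gas_accel = 1, accel_until = 0,
                             ramp_breaths = 0L, init = NULL) {
  stopifnot(inherits(patient, "virtual_patient"), dt > 0, duration > 0)
  bound <- .dt_stability_bound(patient)
  if (dt > bound)
    stop(sprintf("dt = %g s exceeds the stability bound %.4g s for this patient",
                 dt, bound))
  ctrl <- list(dt = dt, duration = duration, store_from = store_from,
               store_every = as.integer(store_every), gas_accel = gas_accel,
               accel_until = accel_until,
               n_ds_slices = .aprvdp_const$n_ds_slices,
               u_close = .aprvdp_const$u_close,
               tau_venous = .aprvdp_const$tau_venous,
               ramp_breaths = as.integer(ramp_breaths))
  res <- .cpp_sim_run(.patient_for_cpp(patient), .vent_for_cpp(vent), ctrl,
                      init)
  tr <- as.data.frame(res$trace)
  names(tr) <- c("time_s", "paw_cmH2O", "plung_cmH2O", "flow_L_s",
                 "volume_L", "pao2_mmHg", "paco2_mmHg", "petco2_mmHg",
                 "n_open")
  structure(list(trace = tr, state = res$state,
                 o2_uptake_ml = res$o2_uptake_ml,
                 co2_output_ml = res$co2_output_ml,
                 window_s = res$window_s, vent = vent, patient = patient),
            class = "lung_run")
}

#' Relaxed (zero-pressure) lung volume of a patient
#'
#' Applies zero airway pressure and lets the mechanics equilibrate,
#' reporting the end-expiratory lung volume (compartments plus dead
#' space).  For the healthy reference patient this is the functional
#' residual capacity.
#'
#' @param patient a [virtual_patient()].
#' @param settle settling time (s).
#' @param dt integration step (s).
#' @return Relaxed volume (L).
#' @export
relaxed_lung_volume <- function(patient, settle = 10, dt = 0.001) {
  vent <- aprv_settings(p_high = 2, p_low = 0, t_high = 0.5,
                        t_low = settle - 0.5)
  run <- simulate_patient(patient, vent, duration = settle, dt = dt,
                          store_from = settle - dt * 2)
  tail(run$trace$volume_L, 1)
}

# ---- blood gas helpers ---------------------------------------------------

#' Oxyhaemoglobin saturation and blood gas contents
#'
#' `o2_saturation` is the Severinghaus saturation curve; `o2_blood_content`
#' adds carried plus dissolved O2; `co2_blood_content` is a linearised CO2
#' dissociation curve; `po2_from_content` inverts the O2 content curve.
#'
#' @param po2,pco2 gas tensions (mmHg).
#' @param hb haemoglobin (g/L).
#' @param content blood gas content (mL/L).
#' @return Saturation (fraction), contents (mL/L), or tension (mmHg).
#' @export
o2_saturation <- function(po2) {
  ifelse(po2 <= 0, 0, 1 / (1 + 23400 / (po2^3 + 150 * po2)))
}

#' @rdname o2_saturation
#' @export
o2_blood_content <- function(po2, hb) 1.34 * hb * o2_saturation(po2) + 0.03 * po2

#' @rdname o2_saturation
#' @export
co2_blood_content <- function(pco2) 480 + 4.7 * (pco2 - 40)

#' @rdname o2_saturation
#' @export
po2_from_content <- function(content, hb) .cpp_po2_from_content(content, hb)

#' Steady-state arterial and mixed-venous blood gases
#'
#' Mixes perfusion-weighted end-capillary blood (equilibrated with the
#' per-compartment alveolar tensions) with shunted mixed-venous blood.
#' When `mixed_venous` is not supplied, the mixed-venous contents are
#' solved from the Fick steady state: `Cv = Ca - VO2/CO` for oxygen and
#' `Cv = Ca + RQ*VO2/CO` for carbon dioxide, which requires a total shunt
#' fraction below 1.
#'
#' @param pa_o2,pa_co2 alveolar tensions (mmHg) per perfused open
#'   compartment.
#' @param weights perfusion weights of those compartments plus (last
#'   element) the total shunt fraction; must sum to 1.
#' @param patient a [virtual_patient()] supplying Hb, VO2, RQ and cardiac
#'   output.
#' @param mixed_venous optional list with `cv_o2`, `cv_co2` contents
#'   (mL/L); when given, the Fick solve is skipped.
#' @return List with `pao2`, `paco2`, `pvo2`, `pvco2` (mmHg) and the
#'   underlying contents.
#' @export
blood_gas <- function(pa_o2, pa_co2, weights, patient, mixed_venous = NULL) {
  if (patient$hb <= 0) stop("'hb' must be positive")
  stopifnot(length(weights) == length(pa_o2) + 1)
  if (abs(sum(weights) - 1) > 1e-6)
    stop("perfusion weights (including shunt) must sum to 1")
  f_sh <- weights[length(weights)]
  w <- weights[-length(weights)]
  cc_o2 <- o2_blood_content(pa_o2, patient$hb)
  cc_co2 <- co2_blood_content(pa_co2)
  mo2 <- sum(w * cc_o2); mco2 <- sum(w * cc_co2)
  vo2 <- patient$vo2; co <- patient$cardiac_output
  if (is.null(mixed_venous)) {
    if (f_sh >= 1)
      stop("total shunt of 1 has no Fick steady state; supply 'mixed_venous'")
    # Ca = mixed capillary + f_sh * Cv and Cv = Ca -/+ metabolic flux
    ca_o2 <- (mo2 - f_sh * vo2 / co) / (1 - f_sh)
    cv_o2 <- ca_o2 - vo2 / co
    ca_co2 <- (mco2 + f_sh * patient$rq * vo2 / co) / (1 - f_sh)
    cv_co2 <- ca_co2 + patient$rq * vo2 / co
  } else {
    cv_o2 <- mixed_venous$cv_o2; cv_co2 <- mixed_venous$cv_co2
    ca_o2 <- mo2 + f_sh * cv_o2
    ca_co2 <- mco2 + f_sh * cv_co2
  }
  list(pao2 = as.numeric(po2_from_content(ca_o2, patient$hb)),
       paco2 = (ca_co2 - 480) / 4.7 + 40,
       pvo2 = as.numeric(po2_from_content(max(cv_o2, 1), patient$hb)),
       pvco2 = (cv_co2 - 480) / 4.7 + 40,
       ca_o2 = ca_o2, ca_co2 = ca_co2, cv_o2 = cv_o2, cv_co2 = cv_co2)
}

#' Total shunt fraction consistent with a target oxygenation
#'
#' Solves the venous-admixture equation for the shunt fraction that yields
#' a given PaO2 at a given inspired O2 fraction, using the alveolar gas
#' equation for the ideal-compartment tension.  Used to seed cohort
#' generation and calibration.
#'
#' @param pao2 target arterial O2 tension (mmHg).
#' @param fio2 inspired O2 fraction.
#' @param paco2 arterial CO2 tension (mmHg).
#' @param hb haemoglobin (g/L).
#' @param vo2 O2 consumption (mL/min).
#' @param co cardiac output (L/min).
#' @param rq respiratory quotient.
#' @return Shunt fraction in `[0, 0.95]`.
#' @export
shunt_for_pf <- function(pao2, fio2, paco2 = 45, hb = 120, vo2 = 250,
                         co = 5, rq = 0.8) {
  pao2_alv <- fio2 * .aprvdp_const$p_dry - paco2 / rq
  cc <- o2_blood_content(pao2_alv, hb)
  ca <- o2_blood_content(pao2, hb)
  x <- max(cc - ca, 0) * co / vo2
  min(x / (1 + x), 0.95)
}
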