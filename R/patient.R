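# Virtual patient construction and (de)serialisation.

#' Parameter bounds for the calibrated patient vector
#'
#' Allowable ranges for the per-compartment parameters (extrinsic pressure
#' `P_ext`, stiffness `k_stiff`, threshold opening pressure `TOP`) and the
#' whole-body parameters varied during calibration.
#'
#' @return A named list of length-2 numeric vectors `c(lower, upper)`.
#' @export
patient_bounds <- function() {
  list(
    p_ext = c(-50, 28.8),
    k_stiff = c(-2, 1),
    top = c(5, 100),        # cmH2O
    rq = c(0.7, 0.9),
    vo2 = c(150, 300),      # mL/min
    hb = c(90, 160),        # g/L
    shunt_anat = c(1, 2),   # percent
    vd = c(60, 150)         # mL
  )
}

#' Construct a virtual patient
#'
#' A virtual patient is the full parameterisation of the lung model: 100
#' alveolar compartments (each with an extrinsic pressure offset, a
#' stiffness index and a threshold opening pressure) plus whole-body gas
#' exchange parameters.  Each compartment rests at a reference volume
#' `v_ref` chosen so that the healthy lung of the given body mass holds
#' `2.5 * body_mass / 70` litres (including the anatomical dead space) at
#' zero airway pressure.
#'
#' @param p_ext numeric vector of extrinsic pressures (cmH2O), one per
#'   compartment.
#' @param k_stiff numeric vector of dimensionless stiffness indices; the
#'   local elastance scales with `exp(k_stiff)`.
#' @param top numeric vector of threshold opening pressures (cmH2O).
#' @param rq respiratory quotient.
#' @param vo2 total oxygen consumption (mL/min).
#' @param hb haemoglobin (g/L).
#' @param shunt_anat anatomical shunt (percent of cardiac output).
#' @param vd anatomical dead-space volume (mL).
#' @param body_mass predicted body weight (kg).
#' @param cardiac_output blood flow (L/min).
#' @param r_b expiratory bronchiolar inlet resistance per compartment
#'   (cmH2O/(L/s)), recycled to the number of compartments.
#' @param r_b_insp inspiratory bronchiolar resistance (cmH2O/(L/s));
#'   dynamic airway compression makes expiration the slower phase, so the
#'   default is lower than `r_b`.
#' @param r_c shared central airway resistance (cmH2O/(L/s)).
#' @param n_compartments number of alveolar compartments (100 for the
#'   standard model; oracle patients may use fewer).
#' @param check validate parameter ranges (disable only for test fixtures).
#' @return An object of class `virtual_patient`.
#' @export
virtual_patient <- function(p_ext, k_stiff, top, rq = 0.8, vo2 = 250,
                            hb = 120, shunt_anat = 1.5, vd = 100,
                            body_mass = 70, cardiac_output = 5,
                            r_b = .aprvdp_const$r_b_default,
                            r_b_insp = .aprvdp_const$r_b_insp_default,
                            r_c = .aprvdp_const$r_c_default,
                            n_compartments = 100, check = TRUE) {
  p_ext <- rep_len(as.numeric(p_ext), n_compartments)
  k_stiff <- rep_len(as.numeric(k_stiff), n_compartments)
  top <- rep_len(as.numeric(top), n_compartments)
  r_b <- rep_len(as.numeric(r_b), n_compartments)
  r_b_insp <- rep_len(as.numeric(r_b_insp), n_compartments)
  if (check) {
    bd <- patient_bounds()
    chk <- function(x, nm) {
      r <- bd[[nm]]
      if (any(x < r[1] - 1e-9 | x > r[2] + 1e-9))
        stop(sprintf("'%s' outside allowable range [%g, %g]", nm, r[1], r[2]))
    }
    chk(p_ext, "p_ext"); chk(k_stiff, "k_stiff"); chk(top, "top")
    chk(rq, "rq"); chk(vo2, "vo2"); chk(hb, "hb")
    chk(shunt_anat, "shunt_anat"); chk(vd, "vd")
    if (any(r_b <= 0) || any(r_b_insp <= 0)) stop("'r_b' must be positive")
    if (hb <= 0) stop("'hb' must be positive")
  }
  frc_ref <- .aprvdp_const$frc_per_kg * body_mass
  v_ref <- (frc_ref - vd / 1000) / n_compartments
  if (v_ref <= 0) stop("dead space exceeds the reference lung volume")
  structure(list(
    p_ext = p_ext, k_stiff = k_stiff, top = top, r_b = r_b,
    r_b_insp = r_b_insp,
    rq = rq, vo2 = vo2, hb = hb, shunt_anat = shunt_anat, vd = vd / 1000,
    body_mass = body_mass, cardiac_output = cardiac_output,
    r_c = r_c, v_ref = v_ref,
    pv_a = .aprvdp_const$pv_a, pv_b = .aprvdp_const$pv_b,
    linear = FALSE, c_lin = 0
  ), class = "virtual_patient")
}

#' Healthy 70-kg reference patient
#'
#' All compartments have zero extrinsic pressure and nominal stiffness, so
#' the relaxed lung holds its reference functional residual capacity of
#' 2.5 L (scaled by body mass) at zero airway pressure.
#'
#' @param body_mass predicted body weight (kg).
#' @inheritParams virtual_patient
#' @return A `virtual_patient`.
#' @export
healthy_reference_patient <- function(body_mass = 70, vd = 100) {
  virtual_patient(p_ext = 0, k_stiff = 0, top = 5, body_mass = body_mass,
                  vd = vd)
}

#' Single-compartment linear test patient
#'
#' A one-compartment lung with a linear pressure-volume law
#' `P = P_ext + (v - v_ref) / C` and a single airway resistance, for which
#' pressure, flow and volume during a pressure step follow a closed-form
#' mono-exponential.  Used as the analytic oracle for the simulator and the
#' driving-pressure estimators.
#'
#' @param resistance total airway resistance (cmH2O/(L/s)); split between
#'   the central and bronchiolar segment internally.
#' @param compliance compartment compliance (L/cmH2O).
#' @param v_ref resting volume at zero pressure (L).
#' @param vd dead-space volume (mL).
#' @return A `virtual_patient` with `linear = TRUE` and one compartment.
#' @export
linear_single_compartment_patient <- function(resistance = 10,
                                              compliance = 0.05,
                                              v_ref = 2.4, vd = 100) {
  p <- virtual_patient(p_ext = 0, k_stiff = 0, top = 5, vd = vd,
                       n_compartments = 1, r_b = resistance / 2,
                       r_b_insp = resistance / 2,
                       r_c = resistance / 2, check = FALSE)
  p$v_ref <- v_ref
  p$linear <- TRUE
  p$c_lin <- compliance
  p
}

#' @export
print.virtual_patient <- function(x, ...) {
  n <- length(x$p_ext)
  cat(sprintf("<virtual_patient> %d compartments, %s PV law\n", n,
              if (x$linear) "linear" else "exponential"))
  cat(sprintf("  TOP mean %.1f cmH2O | P_ext mean %.1f | k_stiff mean %.2f\n",
              mean(x$top), mean(x$p_ext), mean(x$k_stiff)))
  cat(sprintf("  RQ %.2f  VO2 %.0f mL/min  Hb %.0f g/L  Shunt_anat %.1f%%  VD %.0f mL\n",
              x$rq, x$vo2, x$hb, x$shunt_anat, x$vd * 1000))
  invisible(x)
}

# convert to the flat list the compiled core expects
.patient_for_cpp <- function(p) {
  list(p_ext = p$p_ext, k_stiff = p$k_stiff, top = p$top, r_b = p$r_b,
       r_b_insp = p$r_b_insp,
       v_ref = p$v_ref, pv_a = p$pv_a, pv_b = p$pv_b,
       linear = p$linear, c_lin = as.numeric(p$c_lin),
       r_c = p$r_c, rq = p$rq, vo2 = p$vo2, hb = p$hb,
       shunt_anat = p$shunt_anat, vd = p$vd, cardiac_output = p$cardiac_output)
}

#' Write / read a patient parameter file
#'
#' Plain-text format: a block of `key value` pairs for the whole-body
#' parameters followed by a CSV table of the per-compartment triples.
#'
#' @param patient a `virtual_patient`.
#' @param path file path.
#' @return `write_patient` returns `path` invisibly; `read_patient` returns
#'   a `virtual_patient`.
#' @export
write_patient <- function(patient, path) {
  scal <- c(rq = patient$rq, vo2 = patient$vo2, hb = patient$hb,
            shunt_anat = patient$shunt_anat, vd_ml = patient$vd * 1000,
            body_mass = patient$body_mass,
            cardiac_output = patient$cardiac_output, r_c = patient$r_c)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%s %.10g", names(scal), scal), con)
  writeLines("", con)
  writeLines("compartment,p_ext,k_stiff,top,r_b,r_b_insp", con)
  writeLines(sprintf("%d,%.10g,%.10g,%.10g,%.10g,%.10g",
                     seq_along(patient$p_ext), patient$p_ext,
                     patient$k_stiff, patient$top, patient$r_b,
                     patient$r_b_insp), con)
  invisible(path)
}

#' @rdname write_patient
#' @export
read_patient <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")[1]
  kv <- do.call(rbind, strsplit(lines[seq_len(blank - 1)], " "))
  scal <- setNames(as.numeric(kv[, 2]), kv[, 1])
  comp <- read.csv(text = paste(lines[(blank + 1):length(lines)],
                                collapse = "\n"))
  virtual_patient(p_ext = comp$p_ext, k_stiff = comp$k_stiff, top = comp$top,
                  rq = scal[["rq"]], vo2 = scal[["vo2"]], hb = scal[["hb"]],
                  shunt_anat = scal[["shunt_anat"]], vd = scal[["vd_ml"]],
                  body_mass = scal[["body_mass"]],
                  cardiac_output = scal[["cardiac_output"]],
                  r_b = comp$r_b, r_b_insp = comp$r_b_insp,
                  r_c = scal[["r_c"]], n_compartments = nrow(comp))
}
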