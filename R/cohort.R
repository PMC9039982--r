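# Synthetic ARDS cohort generation (emulation of a trial-like target set).

#' Cohort specification
#'
#' Describes a synthetic ARDS cohort: its size, the severity mixture
#' (fractions with severe / moderate / mild disease by Berlin PaO2/FiO2
#' bands), and the random seed.  The default mixture is 26% severe, 61%
#' moderate, 13% mild.
#'
#' @param n_patients number of patients.
#' @param severity_mix named fractions `severe`, `moderate`, `mild`; must
#'   sum to 1.
#' @param seed integer seed.
#' @param body_mass predicted body weight (kg) used for the 6 mL/kg tidal
#'   volume.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 90,
                        severity_mix = c(severe = 0.26, moderate = 0.61,
                                         mild = 0.13),
                        seed = 1, body_mass = 70) {
  if (abs(sum(severity_mix) - 1) > 1e-9)
    stop("severity fractions must sum to 1")
  if (n_patients < 1) stop("'n_patients' must be >= 1")
  structure(list(n_patients = n_patients, severity_mix = severity_mix,
                 seed = seed, body_mass = body_mass),
            class = "cohort_spec")
}

#' Largest-remainder apportionment of counts
#'
#' Rounds `n * fractions` to integers that sum exactly to `n`, giving the
#' extra units to the largest remainders.
#'
#' @param n total count.
#' @param fractions numeric fractions summing to 1.
#' @return Integer vector of counts summing to `n`.
#' @export
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    give <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

# ARDSNet-style FiO2/PEEP ladder (lower-PEEP table)
.peep_for_fio2 <- function(fio2) {
  br <- c(0.45, 0.55, 0.65, 0.75, 0.85, 0.95, Inf)
  pe <- c(5, 8, 8, 10, 12, 14, 16)
  pe[findInterval(fio2, br) + 1]
}

# per-severity sampling parameters: P/F band (mmHg), FiO2 range, and
# plausibility ranges for the provisional-patient template
.severity_bands <- list(
  severe = list(pf = c(60, 100), fio2 = c(0.7, 1.0), pext_mu = c(4, 10),
                kstiff_mu = c(0.2, 0.4)),
  moderate = list(pf = c(100, 200), fio2 = c(0.5, 0.8), pext_mu = c(2, 8),
                  kstiff_mu = c(0.05, 0.25)),
  mild = list(pf = c(200, 300), fio2 = c(0.4, 0.6), pext_mu = c(0, 5),
              kstiff_mu = c(-0.05, 0.15))
)

#' Generate a synthetic ARDS cohort of calibration targets
#'
#' Emulates a trial-like cohort with no external data: severities are
#' apportioned by largest remainder; each record samples a PaO2/FiO2
#' ratio uniformly within its Berlin band (severe <= 100, moderate
#' 100-200, mild 200-300 mmHg), an FiO2 increasing with severity, and a
#' PEEP from an FiO2/PEEP ladder.  A provisional severity-matched virtual
#' patient (built with the distribution encoding, its non-aerated
#' fraction chosen to match the record's oxygenation) is simulated at the
#' record's settings to supply mechanically consistent `PIP`, `Pplat` and
#' `Vfrc` targets (each then perturbed by +/-5%) and CO2 targets
#' (perturbed by +/-3%).  Tidal volume is 6 mL/kg of predicted
#' body weight and the mean threshold opening pressure target is
#' 30 cmH2O for every record.
#'
#' @param spec a [cohort_spec()].
#' @param sim_opts simulation options for the provisional patients, see
#'   [cal_sim_opts()].
#' @return A data.frame of class `cohort_targets` with one row per
#'   patient: columns `PaO2, PaCO2, PeCO2, PIP, Pplat, TOPmean, Vfrc, VT,
#'   FiO2, PEEP, RR, DC` plus `id`, `severity`, `PF`.
#' @export
generate_cohort <- function(spec = cohort_spec(), sim_opts = cal_sim_opts()) {
  set.seed(spec$seed)
  counts <- largest_remainder(spec$n_patients, spec$severity_mix)
  sev <- rep(names(spec$severity_mix), counts)
  n <- spec$n_patients
  vt <- 0.006 * spec$body_mass  # L, 6 mL/kg predicted body weight

  rows <- lapply(seq_len(n), function(i) {
    b <- .severity_bands[[sev[i]]]
    # 4-mmHg margin keeps the record inside its band after the secant
    # match of the achievable PaO2
    pf <- runif(1, b$pf[1] + 4, b$pf[2] - 4)
    fio2 <- round(runif(1, b$fio2[1], b$fio2[2]), 2)
    pao2 <- pf * fio2
    peep <- .peep_for_fio2(fio2)
    rr <- round(runif(1, 16, 28))
    dc <- round(runif(1, 0.30, 0.45), 2)

    # provisional patient: non-aerated fraction tuned (secant iteration on
    # the simulated PaO2) so the record's oxygenation target is actually
    # achievable by the model at its fixed settings
    s_tot <- shunt_for_pf(pao2, fio2, paco2 = 40)
    # non-aerated compartments need thresholds above peak pressures to
    # stay collapsed; with the compartment-mean threshold fixed at 30
    # cmH2O that caps the stably closed fraction near 0.41
    f_closed <- min(max(s_tot - 0.015, 0.02), 0.41)
    mk_genes <- function(fc, base) {
      n_c <- max(round(100 * fc), 1); n_o <- 100 - n_c
      top_c <- 62
      top_o <- max((3000 - n_c * top_c) / max(n_o, 1), 5)
      base[1] <- fc; base[8] <- top_o; base[10] <- top_c
      base
    }
    base_genes <- c(f_closed,
                    runif(1, b$pext_mu[1], b$pext_mu[2]), runif(1, 3, 6),
                    27.5, 1,
                    runif(1, b$kstiff_mu[1], b$kstiff_mu[2]),
                    runif(1, 0.3, 0.5),
                    17, 5, 60, 6,
                    runif(1, 0.75, 0.85), runif(1, 200, 260),
                    runif(1, 100, 140), runif(1, 1, 2), runif(1, 80, 130))
    tg0 <- list(VT = vt, FiO2 = fio2, PEEP = peep, RR = rr, DC = dc)
    eval_fc <- function(fc) {
      prov <- decode_virtual_patient(mk_genes(fc, base_genes),
                                     "distribution",
                                     body_mass = spec$body_mass)
      list(y = baseline_outputs(prov, tg0, sim_opts), fc = fc)
    }
    lo <- c(0.02, NA); hi <- c(0.41, NA)
    cur <- eval_fc(f_closed)
    for (it in 1:8) {
      err <- cur$y[["PaO2"]] - pao2
      if (abs(err) <= 1.5) break
      if (err > 0) lo <- c(cur$fc, err) else hi <- c(cur$fc, err)
      # more closed compartments -> more shunt -> lower PaO2
      fc_new <- if (err > 0) min(cur$fc + max(0.03, abs(err) / 400), hi[1])
                else max(cur$fc - max(0.03, abs(err) / 400), lo[1])
      if (!is.na(lo[2]) && !is.na(hi[2]))
        fc_new <- (lo[1] + hi[1]) / 2  # bracketed: bisect
      if (abs(fc_new - cur$fc) < 1e-3) break
      cur <- eval_fc(fc_new)
    }
    y0 <- cur$y
    # record the achievable tension, clamped into the assigned band
    pao2 <- min(max(y0[["PaO2"]], (b$pf[1] + 0.5) * fio2),
                (b$pf[2] - 0.5) * fio2)
    pf <- pao2 / fio2

    paco2 <- y0[["PaCO2"]] * runif(1, 0.97, 1.03)
    peco2 <- min(y0[["PeCO2"]] * runif(1, 0.97, 1.03), paco2 - 0.5)

    rec <- data.frame(
      id = i, severity = sev[i], PF = pf,
      PaO2 = pao2, PaCO2 = paco2, PeCO2 = peco2,
      PIP = y0[["PIP"]] * runif(1, 0.95, 1.05),
      Pplat = y0[["Pplat"]] * runif(1, 0.95, 1.05),
      TOPmean = 30,
      Vfrc = y0[["Vfrc"]] * runif(1, 0.95, 1.05),
      VT = vt, FiO2 = fio2, PEEP = peep, RR = rr, DC = dc)
    attr(rec, "provisional_genes") <- mk_genes(cur$fc, base_genes)
    rec
  })
  out <- do.call(rbind, rows)
  # synthetic ground-truth parameterisations, kept as metadata for
  # diagnostics; the calibrator never sees them
  attr(out, "provisional_genes") <- lapply(rows, attr, "provisional_genes")
  class(out) <- c("cohort_targets", class(out))
  out
}

#' Classify ARDS severity from the PaO2/FiO2 ratio
#'
#' Berlin bands: severe <= 100, moderate 100-200, mild 200-300 mmHg.
#'
#' @param pf PaO2/FiO2 ratio (mmHg).
#' @return Character vector of severities.
#' @export
berlin_severity <- function(pf) {
  ifelse(pf <= 100, "severe", ifelse(pf <= 200, "moderate", "mild"))
}

#' Write / read a cohort targets CSV
#'
#' @param targets a `cohort_targets` data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` a
#'   data.frame.
#' @export
write_cohort <- function(targets, path) {
  write.csv(targets, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- read.csv(path)
  need <- c("PaO2", "PaCO2", "PeCO2", "PIP", "Pplat", "TOPmean", "Vfrc",
            "VT", "FiO2", "PEEP")
  if (!all(need %in% names(x)))
    stop("targets CSV must have columns: ", paste(need, collapse = ", "))
  class(x) <- c("cohort_targets", class(x))
  x
}
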