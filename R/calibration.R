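# Calibration of virtual patients to bedside targets with a real-coded
# genetic algorithm.

.target_names <- c("PaO2", "PaCO2", "PeCO2", "PIP", "Pplat", "TOPmean",
                   "Vfrc")

#' Calibration cost
#'
#' Root of the sum of squared relative errors over the seven calibration
#' targets: PaO2, PaCO2, end-tidal CO2, peak inspiratory pressure, plateau
#' pressure, mean threshold opening pressure, and functional residual
#' capacity.  `J = sqrt(sum(((Yhat - Y) / Y)^2))`; zero iff the model
#' reproduces every target exactly.
#'
#' @param y_hat named numeric vector of model outputs (names as in
#'   `Y`).
#' @param y named numeric vector of patient targets; all components must
#'   be strictly positive.
#' @return The scalar cost `J`.
#' @export
calibration_cost <- function(y_hat, y) {
  y <- y[.target_names]; y_hat <- y_hat[.target_names]
  if (any(!is.finite(unlist(y))) || any(unlist(y) <= 0))
    stop("all calibration targets must be strictly positive")
  sqrt(sum(((unlist(y_hat) - unlist(y)) / unlist(y))^2))
}

#' Genetic-algorithm settings
#'
#' Conventional real-coded GA: tournament selection, blend (BLX-alpha)
#' crossover, per-gene Gaussian mutation clipped to bounds, and elitism.
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param tournament tournament size.
#' @param blx_alpha blend-crossover expansion factor.
#' @param p_crossover crossover probability per pair.
#' @param p_mutate per-gene mutation probability.
#' @param mutate_sd mutation standard deviation as a fraction of each
#'   gene's range.
#' @param elitism number of best individuals copied unchanged.
#' @return A list of GA settings.
#' @export
ga_control <- function(pop_size = 50, generations = 100, tournament = 3,
                       blx_alpha = 0.5, p_crossover = 0.9, p_mutate = 0.15,
                       mutate_sd = 0.1, elitism = 1) {
  list(pop_size = pop_size, generations = generations,
       tournament = tournament, blx_alpha = blx_alpha,
       p_crossover = p_crossover, p_mutate = p_mutate,
       mutate_sd = mutate_sd, elitism = elitism)
}

# gene bounds for the two encodings -----------------------------------------

.gene_bounds <- function(encoding, optimize_rr = FALSE) {
  bd <- patient_bounds()
  if (encoding == "distribution") {
    g <- rbind(
      f_closed = c(0, 0.75),
      pext_open_mu = c(-10, 15), pext_open_sd = c(0, 8),
      pext_closed_mu = c(24, 28.8), pext_closed_sd = c(0, 2),
      kstiff_mu = c(-1, 1), kstiff_sd = c(0, 0.8),
      top_open_mu = c(5, 60), top_open_sd = c(0, 15),
      top_closed_mu = c(35, 95), top_closed_sd = c(0, 20),
      rq = bd$rq, vo2 = bd$vo2, hb = bd$hb, shunt_anat = bd$shunt_anat,
      vd = bd$vd)
  } else {
    g <- rbind(
      matrix(rep(bd$p_ext, each = 100), ncol = 2,
             dimnames = list(paste0("p_ext_", 1:100), NULL)),
      matrix(rep(bd$k_stiff, each = 100), ncol = 2,
             dimnames = list(paste0("k_stiff_", 1:100), NULL)),
      matrix(rep(bd$top, each = 100), ncol = 2,
             dimnames = list(paste0("top_", 1:100), NULL)),
      rq = bd$rq, vo2 = bd$vo2, hb = bd$hb, shunt_anat = bd$shunt_anat,
      vd = bd$vd)
  }
  if (optimize_rr)
    g <- rbind(g, rr = c(10, 35), dc = c(0.25, 0.5))
  g
}

# deterministic quantile spread of a group around (mu, sd), clipped
.spread <- function(n, mu, sigma, lo, hi) {
  if (n == 0) return(numeric(0))
  pmin(pmax(mu + sigma * qnorm((seq_len(n) - 0.5) / n), lo), hi)
}

#' Decode a gene vector into a virtual patient
#'
#' The `"full"` encoding carries all 300 compartment parameters plus the
#' five whole-body parameters as genes.  The `"distribution"` encoding
#' describes the compartment population by a closed ("non-aerated")
#' fraction and per-group means and spreads of extrinsic pressure,
#' stiffness and threshold opening pressure; compartment values are laid
#' out on deterministic normal quantiles, so the decode is reproducible
#' and exchangeable.
#'
#' @param genes numeric gene vector (see [calibrate_patient()]).
#' @param encoding `"distribution"` or `"full"`.
#' @param body_mass predicted body weight (kg).
#' @return A `virtual_patient`; when the encoding carries RR/DC genes the
#'   patient gains attributes `rr` and `dc`.
#' @export
decode_virtual_patient <- function(genes, encoding = "distribution",
                                   body_mass = 70) {
  bd <- patient_bounds()
  has_rrdc <- FALSE
  if (encoding == "distribution") {
    if (length(genes) == 18) has_rrdc <- TRUE
    else stopifnot(length(genes) == 16)
    g <- as.numeric(genes)
    n_c <- round(100 * g[1]); n_o <- 100 - n_c
    p_ext <- c(.spread(n_o, g[2], g[3], bd$p_ext[1], bd$p_ext[2]),
               .spread(n_c, g[4], g[5], bd$p_ext[1], bd$p_ext[2]))
    k_stiff <- .spread(100, g[6], g[7], bd$k_stiff[1], bd$k_stiff[2])
    top <- c(.spread(n_o, g[8], g[9], bd$top[1], bd$top[2]),
             .spread(n_c, g[10], g[11], bd$top[1], bd$top[2]))
    p <- virtual_patient(p_ext = p_ext, k_stiff = k_stiff, top = top,
                         rq = g[12], vo2 = g[13], hb = g[14],
                         shunt_anat = g[15], vd = g[16],
                         body_mass = body_mass)
  } else {
    if (length(genes) == 307) has_rrdc <- TRUE
    else stopifnot(length(genes) == 305)
    g <- as.numeric(genes)
    clip <- function(x, r) pmin(pmax(x, r[1]), r[2])
    p <- virtual_patient(
      p_ext = clip(g[1:100], bd$p_ext),
      k_stiff = clip(g[101:200], bd$k_stiff),
      top = clip(g[201:300], bd$top),
      rq = clip(g[301], bd$rq), vo2 = clip(g[302], bd$vo2),
      hb = clip(g[303], bd$hb), shunt_anat = clip(g[304], bd$shunt_anat),
      vd = clip(g[305], bd$vd), body_mass = body_mass)
  }
  if (has_rrdc) {
    n <- length(genes)
    attr(p, "rr") <- min(max(genes[n - 1], 10), 35)
    attr(p, "dc") <- min(max(genes[n], 0.25), 0.5)
  }
  p
}

#' Model outputs at a patient's conventional ventilator settings
#'
#' Simulates the patient under volume-controlled ventilation at the fixed
#' settings of a targets record until cyclic steady state and returns the
#' seven calibration outputs.
#'
#' @param patient a [virtual_patient()].
#' @param targets a targets record (named list / one-row data.frame) with
#'   at least `VT` (L), `FiO2`, `PEEP`, `RR`, `DC`.
#' @param sim_opts list of simulation options: `duration`, `dt`,
#'   `gas_accel`, `accel_cycles`, `store_cycles`.
#' @return Named numeric vector `PaO2, PaCO2, PeCO2, PIP, Pplat, TOPmean,
#'   Vfrc` (tensions mmHg, pressures cmH2O, Vfrc mL).
#' @export
baseline_outputs <- function(patient, targets, sim_opts = cal_sim_opts()) {
  rr <- if (!is.null(attr(patient, "rr"))) attr(patient, "rr") else targets$RR
  dc <- if (!is.null(attr(patient, "dc"))) attr(patient, "dc") else targets$DC
  stg <- vcv_settings(vt = targets$VT, peep = targets$PEEP, rr = rr, dc = dc,
                      fio2 = targets$FiO2)
  run <- run_vcv(patient, stg, duration = sim_opts$duration,
                 dt = sim_opts$dt, store_cycles = sim_opts$store_cycles,
                 gas_accel = sim_opts$gas_accel,
                 accel_cycles = sim_opts$accel_cycles)
  m <- extract_measurements(run)
  c(PaO2 = m$pao2, PaCO2 = m$paco2, PeCO2 = m$petco2, PIP = m$p_peak,
    Pplat = m$p_plat, TOPmean = mean(patient$top), Vfrc = m$v_frc_ml)
}

#' @rdname baseline_outputs
#' @param duration,dt,gas_accel,accel_cycles,store_cycles see
#'   [run_vcv()]; the defaults trade waveform resolution for speed and are
#'   adequate for steady-state calibration outputs.
#' @export
cal_sim_opts <- function(duration = 45, dt = 0.004, gas_accel = 12,
                         accel_cycles = 3, store_cycles = 1) {
  list(duration = duration, dt = dt, gas_accel = gas_accel,
       accel_cycles = accel_cycles, store_cycles = store_cycles)
}

# heuristic gene vectors near the targets (distribution encoding); a small
# family diversified over the weakly identified genes
.heuristic_genes <- function(targets, optimize_rr) {
  s_tot <- shunt_for_pf(targets$PaO2, targets$FiO2, targets$PaCO2)
  f0 <- min(max(s_tot - 0.015, 0.02), 0.72)
  out <- list()
  for (df in c(0, -0.06, 0.06)) {
    for (ks in c(0.1, 0.3)) {
      f_closed <- min(max(f0 + df, 0.02), 0.41)
      n_c <- max(round(100 * f_closed), 1); n_o <- 100 - n_c
      top_closed <- 62
      top_open <- max((3000 - n_c * top_closed) / max(n_o, 1), 5)
      g <- c(f_closed, 6, 4, 27.5, 1, ks, 0.4, top_open, 5, top_closed, 6,
             0.8, 225, 120, 1.5, 100)
      if (optimize_rr) g <- c(g, 18, 0.35)
      out[[length(out) + 1]] <- g
    }
  }
  out
}

#' Calibrate a virtual patient to a targets record
#'
#' Minimises the calibration cost over the parameter space with a
#' real-coded genetic algorithm (followed by an optional Nelder-Mead
#' polish of the best individual).  Each cost evaluation simulates the
#' candidate patient to cyclic steady state under the record's fixed
#' ventilator settings and compares the seven model outputs against the
#' targets.  When `RR`/`DC` are missing from the record they are appended
#' to the gene vector and optimised as well.
#'
#' @param targets named list / one-row data.frame with the seven targets
#'   (`PaO2`, `PaCO2`, `PeCO2` in mmHg; `PIP`, `Pplat` in cmH2O;
#'   `TOPmean` in cmH2O; `Vfrc` in mL) and the fixed settings `VT` (L),
#'   `FiO2`, `PEEP`, and optionally `RR`, `DC`.
#' @param encoding `"distribution"` (default; 16 genes describing the
#'   compartment population) or `"full"` (305 genes, every compartment
#'   parameter free).
#' @param ga a [ga_control()] list.
#' @param seed integer seed; identical targets and seed give identical
#'   results.
#' @param polish_iter Nelder-Mead refinement iterations on the best
#'   individual (0 disables).
#' @param sim_opts simulation options for cost evaluations, see
#'   [cal_sim_opts()].
#' @param verbose print per-generation progress.
#' @return A `calibration_result` list: `patient`, `genes`, `J`,
#'   `model_outputs`, `targets`, `converged` (J <= 0.15), `evaluations`,
#'   and `history` (best J per generation).
#' @export
calibrate_patient <- function(targets, encoding = c("distribution", "full"),
                              ga = ga_control(), seed = 1,
                              polish_iter = 50, sim_opts = cal_sim_opts(),
                              verbose = FALSE) {
  encoding <- match.arg(encoding)
  targets <- as.list(targets)
  y <- unlist(targets[.target_names])
  if (length(y) != length(.target_names) || any(!is.finite(y)) ||
      any(y <= 0))
    stop("all seven calibration targets must be present and positive")
  optimize_rr <- is.null(targets$RR) || is.na(targets$RR) ||
    is.null(targets$DC) || is.na(targets$DC)
  bounds <- .gene_bounds(encoding, optimize_rr)
  lower <- bounds[, 1]; upper <- bounds[, 2]
  ng <- nrow(bounds)
  n_eval <- 0L

  fn <- function(genes) {
    n_eval <<- n_eval + 1L
    p <- decode_virtual_patient(genes, encoding)
    y_hat <- tryCatch(baseline_outputs(p, targets, sim_opts),
                      error = function(e) NULL)
    if (is.null(y_hat) || any(!is.finite(y_hat))) return(100)
    calibration_cost(y_hat, y)
  }

  set.seed(seed)
  pop <- matrix(runif(ga$pop_size * ng, lower, upper), nrow = ga$pop_size,
                byrow = TRUE)
  if (encoding == "distribution") {
    hs <- .heuristic_genes(targets, optimize_rr)
    n_h <- min(max(1, floor(ga$pop_size / 3)), length(hs) * 2)
    for (i in seq_len(n_h)) {
      h <- hs[[(i - 1) %% length(hs) + 1]]
      jit <- h * (1 + rnorm(ng, 0, 0.04)) + rnorm(ng, 0, 0.02 * (upper - lower))
      pop[i, ] <- pmin(pmax(jit, lower), upper)
    }
  }
  fit <- apply(pop, 1, fn)
  history <- numeric(ga$generations)

  for (gen in seq_len(ga$generations)) {
    ord <- order(fit)
    elite <- pop[ord[seq_len(ga$elitism)], , drop = FALSE]
    elite_fit <- fit[ord[seq_len(ga$elitism)]]
    newpop <- matrix(NA_real_, ga$pop_size, ng)
    newfit <- numeric(ga$pop_size)
    newpop[seq_len(ga$elitism), ] <- elite
    newfit[seq_len(ga$elitism)] <- elite_fit
    for (i in seq(ga$elitism + 1, ga$pop_size)) {
      pick <- function() {
        cand <- sample.int(ga$pop_size, ga$tournament)
        pop[cand[which.min(fit[cand])], ]
      }
      p1 <- pick(); p2 <- pick()
      child <- if (runif(1) < ga$p_crossover) {
        lo <- pmin(p1, p2); hi <- pmax(p1, p2); d <- hi - lo
        runif(ng, lo - ga$blx_alpha * d, hi + ga$blx_alpha * d)
      } else p1
      mut <- runif(ng) < ga$p_mutate
      child[mut] <- child[mut] +
        rnorm(sum(mut), 0, ga$mutate_sd * (upper - lower)[mut])
      child <- pmin(pmax(child, lower), upper)
      newpop[i, ] <- child
      newfit[i] <- fn(child)
    }
    pop <- newpop; fit <- newfit
    history[gen] <- min(fit)
    if (verbose)
      message(sprintf("generation %d: best J = %.4f", gen, min(fit)))
  }

  best <- which.min(fit)
  best_genes <- pop[best, ]
  best_J <- fit[best]

  if (polish_iter > 0) {
    fn_pen <- function(g) {
      gc <- pmin(pmax(g, lower), upper)
      fn(gc) + sum(pmax(lower - g, 0) + pmax(g - upper, 0))
    }
    op <- optim(best_genes, fn_pen, method = "Nelder-Mead",
                control = list(maxit = polish_iter, reltol = 1e-4))
    if (op$value < best_J) {
      best_genes <- pmin(pmax(op$par, lower), upper)
      best_J <- fn(best_genes)
    }
  }

  patient <- decode_virtual_patient(best_genes, encoding)
  y_hat <- baseline_outputs(patient, targets, sim_opts)
  structure(list(patient = patient, genes = setNames(best_genes,
                                                     rownames(bounds)),
                 J = best_J, model_outputs = y_hat, targets = targets,
                 converged = best_J <= 0.15, evaluations = n_eval,
                 history = history, encoding = encoding, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> J = %.4f (%s encoding, %d evaluations)%s\n",
              x$J, x$encoding, x$evaluations,
              if (x$converged) "" else "  [NOT converged]"))
  tab <- rbind(target = unlist(x$targets[.target_names]),
               model = x$model_outputs[.target_names])
  print(round(tab, 1))
  invisible(x)
}

#' Generate self-consistent targets from a known patient
#'
#' Simulates a known virtual patient at given ventilator settings and
#' returns its outputs formatted as a calibration targets record: the
#' parameter-recovery oracle for the calibrator.
#'
#' @param patient a [virtual_patient()].
#' @param vt,fio2,peep,rr,dc fixed conventional-ventilation settings
#'   (`vt` in L).
#' @param sim_opts see [cal_sim_opts()].
#' @return A targets list suitable for [calibrate_patient()].
#' @export
targets_from_patient <- function(patient, vt = 0.42, fio2 = 0.6, peep = 8,
                                 rr = 18, dc = 0.35,
                                 sim_opts = cal_sim_opts()) {
  tg <- list(VT = vt, FiO2 = fio2, PEEP = peep, RR = rr, DC = dc)
  y <- baseline_outputs(patient, tg, sim_opts)
  c(as.list(y), tg)
}
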