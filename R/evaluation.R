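# Study orchestration and method-comparison statistics.

#' Bland-Altman method comparison
#'
#' Differences are `estimate - truth`; the bias is their mean, and the
#' limits of agreement are the bias +/- 1.96 sample standard deviations.
#'
#' @param truth,estimates equal-length numeric vectors (length >= 2).
#' @return A `bland_altman` list: `bias`, `sd`, `loa_low`, `loa_high`,
#'   `n`, and the differences.
#' @export
bland_altman <- function(truth, estimates) {
  if (length(truth) != length(estimates))
    stop("'truth' and 'estimates' must have equal length")
  if (length(truth) < 2) stop("need at least 2 pairs")
  d <- estimates - truth
  bias <- mean(d); s <- sd(d)
  structure(list(bias = bias, sd = s, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, n = length(d),
                 differences = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.2f, SD %.2f, LOA [%.2f, %.2f], n = %d\n",
              x$bias, x$sd, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Pearson correlation with significance test
#'
#' Thin wrapper over [stats::cor.test()] returning the coefficient and
#' the two-sided p-value.
#'
#' @param x,y equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return List with `r` and `p_value`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("'x' and 'y' must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Bland-Altman panel plot
#'
#' @param ba a [bland_altman()] result.
#' @param x horizontal variable (defaults to the truth-axis values if
#'   supplied, else the pair index).
#' @param xlab,ylab,main plot annotation.
#' @return Invisibly, `ba`.
#' @export
plot_bland_altman <- function(ba, x = seq_along(ba$differences),
                              xlab = "True driving pressure (cmH2O)",
                              ylab = "Estimation error (cmH2O)",
                              main = "") {
  graphics::plot(x, ba$differences, pch = 19, xlab = xlab, ylab = ylab, main = main,
       ylim = range(c(ba$differences, ba$loa_low, ba$loa_high)))
  graphics::abline(h = ba$bias, lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}

#' Run the full in-silico driving-pressure study
#'
#' Orchestrates the complete pipeline: generate (or accept) a cohort of
#' calibration targets, calibrate each patient with the genetic
#' algorithm, ventilate every calibrated patient under APRV at each
#' requested `P_high`/`P_low` setting (T_high = 5 s, T_low = 0.5 s) to
#' cyclic steady state, compute the true driving pressure and the four
#' bedside estimates, and summarise per-setting means, Bland-Altman
#' blocks per estimator, and Pearson correlations of the true driving
#' pressure with baseline compliance and PaO2/FiO2 ratio.
#'
#' @param targets a `cohort_targets` data.frame (from [generate_cohort()]
#'   or [read_cohort()]); or `NULL` to generate one from `spec`.
#' @param spec a [cohort_spec()] used when `targets` is `NULL`.
#' @param settings list of `c(p_high, p_low)` pairs (cmH2O).
#' @param seed integer master seed; per-patient calibration seeds derive
#'   from it.
#' @param ga GA budget for calibration, see [ga_control()].
#' @param polish_iter Nelder-Mead polish iterations per patient.
#' @param sim_opts calibration-evaluation simulation options.
#' @param aprv_duration APRV run length per setting (s).
#' @param aprv_dt integration step for APRV and VCV-switch runs (s).
#' @param vcv whether to compute the VCV-switch estimate.
#' @param verbose log per-patient progress.
#' @return A `cohort_result` list: `reports` (one row per patient and
#'   setting), `summary` (per-setting mean/SD of the true driving
#'   pressure and mean tidal volume per kg), `bland_altman` (per setting
#'   and estimator), `correlations`, `calibration` (per-patient J), and
#'   `patients`.
#' @export
run_study <- function(targets = NULL, spec = cohort_spec(),
                      settings = list(c(30, 5), c(30, 0), c(25, 0)),
                      seed = 1, ga = ga_control(pop_size = 20,
                                                generations = 14),
                      polish_iter = 60, sim_opts = cal_sim_opts(),
                      aprv_duration = 1800, aprv_dt = 0.002, vcv = TRUE,
                      verbose = TRUE) {
  if (is.null(targets)) targets <- generate_cohort(spec, sim_opts)
  n <- nrow(targets)
  set.seed(seed)
  cal_seeds <- sample.int(.Machine$integer.max - 1, n)

  patients <- vector("list", n)
  cal_rows <- vector("list", n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    t0 <- Sys.time()
    cr <- tryCatch(
      calibrate_patient(targets[i, ], encoding = "distribution", ga = ga,
                        seed = cal_seeds[i], polish_iter = polish_iter,
                        sim_opts = sim_opts),
      error = function(e) e)
    if (inherits(cr, "error")) {
      failed <- c(failed, i)
      if (verbose) message(sprintf("patient %d: calibration failed (%s)",
                                   i, conditionMessage(cr)))
      next
    }
    patients[[i]] <- cr$patient
    cal_rows[[i]] <- data.frame(
      id = targets$id[i], J = cr$J, converged = cr$converged,
      evaluations = cr$evaluations, seed = cal_seeds[i],
      runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    if (verbose)
      message(sprintf("patient %d/%d: J = %.3f (%.0f s)", i, n, cr$J,
                      cal_rows[[i]]$runtime_s))
  }
  calibration <- do.call(rbind, cal_rows)

  # baseline compliance from each record's conventional settings
  base_c <- (targets$VT) / (targets$Pplat - targets$PEEP)

  rep_rows <- list()
  for (s in settings) {
    stg <- aprv_settings(p_high = s[1], p_low = s[2])
    for (i in setdiff(seq_len(n), failed)) {
      stg_i <- aprv_settings(p_high = s[1], p_low = s[2],
                             fio2 = targets$FiO2[i])
      run <- suppressWarnings(
        run_aprv(patients[[i]], stg_i, duration = aprv_duration,
                 dt = aprv_dt))
      m <- extract_measurements(run)
      rep <- dp_report(patients[[i]], m, stg_i, rr = targets$RR[i],
                       dc = targets$DC[i], vcv = vcv, dt = aprv_dt)
      rep$id <- targets$id[i]
      rep$p_high <- s[1]; rep$p_low <- s[2]
      rep$setting <- sprintf("%g/%g", s[1], s[2])
      rep$vt_ml_kg <- m$v_released * 1000 / spec$body_mass
      rep$pf_baseline <- targets$PF[i]
      rep$c_baseline <- base_c[i]
      rep$steady <- m$steady
      rep_rows[[length(rep_rows) + 1]] <- rep
    }
  }
  reports <- do.call(rbind, rep_rows)

  est_cols <- c(mono = "dp_mono", tau4 = "dp_tau4", tau3 = "dp_tau3",
                vcv = "dp_vcv")
  if (!vcv) est_cols <- est_cols[names(est_cols) != "vcv"]
  ba_rows <- list(); cor_rows <- list(); sum_rows <- list()
  for (s in settings) {
    key <- sprintf("%g/%g", s[1], s[2])
    sub <- reports[reports$setting == key, ]
    sum_rows[[key]] <- data.frame(
      setting = key, n = nrow(sub),
      dp_true_mean = mean(sub$dp_true), dp_true_sd = sd(sub$dp_true),
      vt_ml_kg_mean = mean(sub$vt_ml_kg))
    for (e in names(est_cols)) {
      d <- sub[[est_cols[e]]] - sub$dp_true
      ba <- if (nrow(sub) >= 2) bland_altman(sub$dp_true, sub[[est_cols[e]]])
            else list(bias = mean(d), sd = NA_real_, loa_low = NA_real_,
                      loa_high = NA_real_, n = nrow(sub))
      ba_rows[[paste(key, e)]] <- data.frame(
        setting = key, estimator = e, bias = ba$bias, sd = ba$sd,
        loa_low = ba$loa_low, loa_high = ba$loa_high, n = ba$n)
    }
    for (v in c("c_baseline", "pf_baseline")) {
      pr <- if (nrow(sub) >= 3 && sd(sub[[v]]) > 0 && sd(sub$dp_true) > 0)
        pearson(sub[[v]], sub$dp_true)
      else list(r = NA_real_, p_value = NA_real_)
      cor_rows[[paste(key, v)]] <- data.frame(
        setting = key, against = v, r = pr$r, p_value = pr$p_value)
    }
  }

  structure(list(
    reports = reports,
    summary = do.call(rbind, c(sum_rows, list(make.row.names = FALSE))),
    bland_altman = do.call(rbind, c(ba_rows, list(make.row.names = FALSE))),
    correlations = do.call(rbind, c(cor_rows, list(make.row.names = FALSE))),
    calibration = calibration, patients = patients, targets = targets,
    failed = failed, settings = settings, seed = seed),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d patients x %d settings (%d failed)\n",
              nrow(x$targets), length(x$settings), length(x$failed)))
  print(x$summary, row.names = FALSE)
  cat("\nBland-Altman (estimate - true dP):\n")
  print(x$bland_altman, row.names = FALSE, digits = 3)
  invisible(x)
}
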