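# Ground-truth OGTT simulation for validation and recovery studies.

#' Specification of a synthetic OGTT subject
#'
#' Defines the ground truth from which sparse, noisy OGTT records are
#' simulated: an open-loop gamma-pulse glucose excursion (the estimator
#' consumes glucose purely as an exogenous input, so no closed-loop
#' glucose-insulin feedback is needed), insulin and c-peptide compartment
#' models driven by it, a sparse sampling schedule, and a measurement-noise
#' level.
#'
#' The defaults reproduce the synthetic validation conditions: glucose in
#' mg/L rising from a 900 mg/L baseline to a 1800 mg/L peak at 30 min and
#' declining through ~1400 mg/L at 60 min back toward baseline by 2-3 h
#' (the textbook course of a normal-subject OGTT),
#' insulin secretion parameters `Km = 0.6` uU/ml/min, `C0 = 1000` mg/L,
#' `alpha = 0.01` per mg/L, sampling at
#' `{-10, 0, 10, 20, 30, 60, 90, 120, 150, 180}` min, and 20% multiplicative
#' Gaussian noise on every sampled value (glucose, insulin and c-peptide),
#' clipped at zero. With `couple_cpeptide = TRUE` the c-peptide model shares
#' `C0` and `alpha`, has `Km` scaled by the 0.056 ng/uU molar constant
#' (exact 1:1 molar co-secretion), and clears twice as slowly as insulin
#' (c-peptide degradation is renal and slower).
#'
#' @param g_baseline fasting glucose (record units).
#' @param g_amplitude peak excursion above baseline.
#' @param t_peak time of the glucose peak (min), `> 0`.
#' @param shape gamma-pulse shape exponent (default 1); larger values give a
#'   narrower pulse with faster decay.
#' @param theta_insulin insulin [model_params()].
#' @param theta_cpeptide c-peptide [model_params()]; defaults to the
#'   molar-coupled model when `couple_cpeptide` is `TRUE`.
#' @param couple_cpeptide derive the c-peptide model from the insulin model
#'   by exact 1:1 molar coupling (ignored when `theta_cpeptide` is given).
#' @param sample_times sparse sampling schedule (min).
#' @param noise_fraction noise level as a fraction of each sampled value
#'   (default 0.20); `0` disables noise.
#' @param noise_type `"multiplicative"` (default; per-sample SD equals
#'   `noise_fraction` of the true value) or `"additive"` (SD equals
#'   `noise_fraction` of the series' time-mean).
#' @param corruption optional `list(time =, factor =, species =)` applied
#'   *after* noise; default species `"glucose"`, emulating a spuriously low
#'   glucose draw (e.g. `factor = 0.6` at 60 min).
#' @param glucose_driver `"interpolant"` (default) drives the hormone models
#'   with the natural cubic spline through the glucose profile *sampled at
#'   the sparse schedule* — the same input the estimator reconstructs from a
#'   noiseless record, so the generate-then-refit loop is exactly closed at
#'   zero noise and noise is the only perturbation studied. `"profile"`
#'   drives with the dense gamma pulse itself, adding the estimator's
#'   sparse-interpolation error to the experiment.
#' @param glucose_unit unit of the glucose quantities above.
#' @param Ts truth-integration step (min).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(g_baseline = 900, g_amplitude = 900, t_peak = 30,
                           shape = 2,
                           theta_insulin = model_params(
                             "single",
                             secretion_params(Km = 0.6, C0 = 1000, alpha = 0.01),
                             tau_p = 15),
                           theta_cpeptide = NULL, couple_cpeptide = TRUE,
                           sample_times = c(-10, 0, 10, 20, 30, 60, 90, 120,
                                            150, 180),
                           noise_fraction = 0.2,
                           noise_type = c("multiplicative", "additive"),
                           corruption = NULL,
                           glucose_driver = c("interpolant", "profile"),
                           glucose_unit = "mg/L", Ts = 0.1) {
  noise_type <- match.arg(noise_type)
  glucose_driver <- match.arg(glucose_driver)
  .check_glucose_unit(glucose_unit)
  stopifnot(inherits(theta_insulin, "model_params"))
  if (!is.finite(t_peak) || t_peak <= 0) stop("'t_peak' must be > 0", call. = FALSE)
  if (g_baseline < 0 || g_amplitude < 0) {
    stop("glucose profile parameters must be >= 0", call. = FALSE)
  }
  if (noise_fraction < 0) stop("'noise_fraction' must be >= 0", call. = FALSE)
  if (length(sample_times) < 4L || any(diff(sample_times) <= 0)) {
    stop("'sample_times' must be >= 4 strictly increasing times", call. = FALSE)
  }
  if (is.null(theta_cpeptide) && couple_cpeptide) {
    s <- theta_insulin$secretion
    theta_cpeptide <- model_params(
      theta_insulin$kind,
      secretion_params(Km = s$Km * molar_csr_per_isr, C0 = s$C0,
                       alpha = s$alpha),
      tau_p = 2 * theta_insulin$tau_p,
      tau_i = if (!is.null(theta_insulin$tau_i)) 2 * theta_insulin$tau_i,
      q1 = theta_insulin$q1, q2 = theta_insulin$q2)
  }
  if (!is.null(corruption)) {
    if (!all(c("time", "factor") %in% names(corruption))) {
      stop("'corruption' needs elements time and factor", call. = FALSE)
    }
    if (is.null(corruption$species)) corruption$species <- "glucose"
    if (!corruption$time %in% sample_times) {
      stop("corruption time must be one of sample_times", call. = FALSE)
    }
  }
  structure(list(g_baseline = g_baseline, g_amplitude = g_amplitude,
                 t_peak = t_peak, shape = shape,
                 theta_insulin = theta_insulin,
                 theta_cpeptide = theta_cpeptide,
                 sample_times = as.numeric(sample_times),
                 noise_fraction = noise_fraction, noise_type = noise_type,
                 corruption = corruption, glucose_driver = glucose_driver,
                 glucose_unit = glucose_unit, Ts = Ts),
            class = "synthetic_spec")
}

#' Gamma-pulse glucose excursion
#'
#' The OGTT-like feeding response: baseline `g_b` before ingestion at t = 0,
#' then \eqn{g_b + A [(t/t_p) e^{1 - t/t_p}]^s} — a smooth single-peaked
#' pulse reaching `g_b + A` exactly at `t = t_p`, returning toward baseline
#' afterwards. Continuous and non-negative everywhere.
#'
#' @param spec a [synthetic_spec()] (only the profile fields are used).
#' @param times evaluation times (min).
#' @return glucose values at `times`.
#' @export
generate_glucose_profile <- function(spec, times) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tt <- pmax(0, times / spec$t_peak)
  spec$g_baseline + spec$g_amplitude * (tt * exp(1 - tt))^spec$shape
}

#' Simulate one synthetic OGTT subject
#'
#' Integrates the insulin and c-peptide models forward (exact zero-order-hold
#' recursion at `Ts`) from their fasting steady states under the gamma-pulse
#' glucose profile, samples glucose and both hormones at the sparse schedule,
#' applies independent per-sample noise (clipped at 0), and finally applies
#' any specified corruption. Fully deterministic for a given `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed for the noise draws.
#' @return an object of class `synthetic_subject`: `truth` (dense
#'   data.frame: `time`, `glucose`, `insulin`, `cpeptide`, `isr`, `csr` at
#'   `Ts` resolution), `record` (the sparse noisy [ogtt_record()]), `spec`,
#'   `seed`.
#' @export
generate_subject <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  st <- spec$sample_times
  Ts <- spec$Ts
  n <- round((st[length(st)] - st[1L]) / Ts)
  tg <- st[1L] + Ts * (0:n)
  if (spec$glucose_driver == "interpolant") {
    sf <- stats::splinefun(st, generate_glucose_profile(spec, st),
                           method = "natural")
    g <- pmax(0, sf(tg))
  } else {
    g <- generate_glucose_profile(spec, tg)
  }
  sim_species <- function(mp) {
    list(plasma = .sim_plasma_grid(mp, g, Ts),
         rate = secretion_rate(g, mp$secretion))
  }
  ins <- sim_species(spec$theta_insulin)
  cpep <- if (!is.null(spec$theta_cpeptide)) sim_species(spec$theta_cpeptide)
  truth <- data.frame(time = tg, glucose = g, insulin = ins$plasma,
                      cpeptide = if (is.null(cpep)) NA_real_ else cpep$plasma,
                      isr = ins$rate,
                      csr = if (is.null(cpep)) NA_real_ else cpep$rate)
  idx <- round((st - st[1L]) / Ts) + 1L
  sampled <- list(glucose = g[idx], insulin = ins$plasma[idx],
                  cpeptide = if (is.null(cpep)) rep(NA_real_, length(st))
                             else cpep$plasma[idx])
  set.seed(seed)
  noisy <- lapply(sampled, function(v) {
    if (spec$noise_fraction == 0 || all(is.na(v))) return(v)
    eps <- stats::rnorm(length(v))
    if (spec$noise_type == "multiplicative") {
      pmax(0, v * (1 + spec$noise_fraction * eps))
    } else {
      pmax(0, v + spec$noise_fraction * mean(v) * eps)
    }
  })
  if (!is.null(spec$corruption)) {
    k <- which(st == spec$corruption$time)
    for (sp in spec$corruption$species) {
      noisy[[sp]][k] <- noisy[[sp]][k] * spec$corruption$factor
    }
  }
  record <- ogtt_record(st, noisy$glucose, noisy$insulin, noisy$cpeptide,
                        subject_id = paste0("synthetic-seed", seed),
                        glucose_unit = spec$glucose_unit)
  structure(list(truth = truth, record = record, spec = spec, seed = seed),
            class = "synthetic_subject")
}

#' Write a synthetic subject to paired CSV files
#'
#' The sparse noisy record goes to `<stem>_record.csv` (standard OGTT CSV,
#' see [read_ogtt()]) and the dense ground truth to `<stem>_truth.csv`.
#'
#' @param subject a [generate_subject()] result.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_subject <- function(subject, stem) {
  stopifnot(inherits(subject, "synthetic_subject"))
  p1 <- paste0(stem, "_record.csv")
  p2 <- paste0(stem, "_truth.csv")
  write_ogtt(subject$record, p1)
  utils::write.csv(subject$truth, p2, row.names = FALSE)
  invisible(c(record = p1, truth = p2))
}

#' Parameter-recovery study on synthetic subjects
#'
#' The generate-then-refit closure experiment: for each plasma degradation
#' time in `taus` and each replicate, simulate a subject, fit the insulin
#' ensemble with [fit_ensemble()], and record the relative errors of the
#' ensemble-mean parameters against the generating values. Replicate-level
#' estimation failures are recorded (`ok = FALSE`) without aborting the
#' table.
#'
#' @param taus generating insulin degradation times (min); default
#'   `{10, 15, 30, 60, 90, 120}`.
#' @param noise_fraction sampling noise level (default 0.20).
#' @param n_reps noise replicates (seeds) per tau.
#' @param n_starts random starts per fit.
#' @param seed master seed; per-replicate generator and fit seeds are
#'   derived deterministically from it.
#' @param bounds fitting bounds; default [validation_bounds()] in the
#'   spec's glucose unit.
#' @param spec_base a [synthetic_spec()] supplying everything except
#'   `tau_p` (noise settings are overridden by `noise_fraction`).
#' @param kind compartment model used for generation and fitting.
#' @return an object of class `recovery_study`: a data.frame with one row
#'   per (tau, replicate) holding the fitted parameter means and relative
#'   errors (`err_*`, as fractions). Summarize with [summary()].
#' @export
recovery_study <- function(taus = c(10, 15, 30, 60, 90, 120),
                           noise_fraction = 0.2, n_reps = 5, n_starts = 100,
                           seed = 1, bounds = NULL,
                           spec_base = synthetic_spec(), kind = "single") {
  stopifnot(inherits(spec_base, "synthetic_spec"))
  if (is.null(bounds)) bounds <- validation_bounds(spec_base$glucose_unit, kind)
  rows <- list()
  for (ti in seq_along(taus)) {
    tau <- taus[ti]
    theta <- spec_base$theta_insulin
    theta_gen <- model_params(kind, theta$secretion, tau_p = tau,
                              tau_i = if (kind == "two_compartment") 2 * tau,
                              q1 = theta$q1, q2 = theta$q2)
    gen <- c(tau_p = tau, Km = theta$secretion$Km, C0 = theta$secretion$C0,
             alpha = theta$secretion$alpha)
    for (rep_i in seq_len(n_reps)) {
      subj_seed <- seed + 1000L * ti + rep_i
      spec <- synthetic_spec(
        g_baseline = spec_base$g_baseline, g_amplitude = spec_base$g_amplitude,
        t_peak = spec_base$t_peak, shape = spec_base$shape,
        theta_insulin = theta_gen, couple_cpeptide = FALSE,
        sample_times = spec_base$sample_times,
        noise_fraction = noise_fraction, noise_type = spec_base$noise_type,
        glucose_unit = spec_base$glucose_unit, Ts = spec_base$Ts)
      subj <- generate_subject(spec, seed = subj_seed)
      ens <- tryCatch(
        fit_ensemble(subj$record, species = "insulin", kind = kind,
                     bounds = bounds, n_starts = n_starts,
                     seed = subj_seed + 500000L),
        error = function(e) NULL)
      if (is.null(ens)) {
        rows[[length(rows) + 1L]] <- data.frame(
          tau = tau, rep = rep_i, seed = subj_seed, ok = FALSE,
          n_accepted = 0L, tau_hat = NA_real_, Km_hat = NA_real_,
          C0_hat = NA_real_, alpha_hat = NA_real_, err_tau = NA_real_,
          err_Km = NA_real_, err_C0 = NA_real_, err_alpha = NA_real_)
        next
      }
      est <- colMeans(ens$params)
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, rep = rep_i, seed = subj_seed, ok = TRUE,
        n_accepted = ens$n_accepted,
        tau_hat = est[["tau_p"]], Km_hat = est[["Km"]],
        C0_hat = est[["C0"]], alpha_hat = est[["alpha"]],
        err_tau = abs(est[["tau_p"]] - gen[["tau_p"]]) / gen[["tau_p"]],
        err_Km = abs(est[["Km"]] - gen[["Km"]]) / gen[["Km"]],
        err_C0 = abs(est[["C0"]] - gen[["C0"]]) / gen[["C0"]],
        err_alpha = abs(est[["alpha"]] - gen[["alpha"]]) / gen[["alpha"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("recovery_study", "data.frame")
  out
}

#' Summarize a recovery study
#'
#' Aggregates the per-replicate relative errors: the seed-averaged `tau_p`
#' error per generating tau (and its maximum across taus), and the mean
#' error over the three secretion-functional parameters (`Km`, `C0`,
#' `alpha`) across all fits. Percentages.
#'
#' @param object a [recovery_study()] table.
#' @param ... unused.
#' @return a list: `per_tau` (data.frame `tau`, `mean_err_tau_pct`),
#'   `tau_max_err_pct`, `secretion_mean_err_pct`, `n_failed`.
#' @export
summary.recovery_study <- function(object, ...) {
  ok <- object[object$ok, , drop = FALSE]
  if (nrow(ok) == 0L) {
    res <- list(per_tau = data.frame(tau = numeric(0L),
                                     mean_err_tau_pct = numeric(0L)),
                tau_max_err_pct = NA_real_,
                secretion_mean_err_pct = NA_real_,
                n_failed = sum(!object$ok))
    class(res) <- "summary.recovery_study"
    return(res)
  }
  per_tau <- stats::aggregate(err_tau ~ tau, data = ok, FUN = mean)
  names(per_tau)[2L] <- "mean_err_tau_pct"
  per_tau$mean_err_tau_pct <- 100 * per_tau$mean_err_tau_pct
  res <- list(per_tau = per_tau,
              tau_max_err_pct = max(per_tau$mean_err_tau_pct),
              secretion_mean_err_pct = 100 * mean(unlist(
                ok[, c("err_Km", "err_C0", "err_alpha")])),
              n_failed = sum(!object$ok))
  class(res) <- "summary.recovery_study"
  res
}

#' @export
print.summary.recovery_study <- function(x, ...) {
  cat("Parameter recovery (relative errors, %)\n")
  print(x$per_tau, digits = 3, row.names = FALSE)
  cat(sprintf("max tau_p error across taus: %.3g%%\n", x$tau_max_err_pct))
  cat(sprintf("mean (Km, C0, alpha) error:  %.3g%%\n", x$secretion_mean_err_pct))
  if (x$n_failed > 0) cat(x$n_failed, "replicate fit(s) failed\n")
  invisible(x)
}
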