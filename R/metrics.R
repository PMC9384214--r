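# Goodness-of-fit metrics, CSR~ISR molar-ratio validation, hepatic
# extraction, and evaluation of the fitted secretion functional.

#' Molar CSR-per-ISR constant
#'
#' Insulin and c-peptide are co-secreted at a 1:1 molar ratio; in the working
#' units (ISR in uU/ml/min, CSR in ng/ml/min) that ratio corresponds to a
#' fixed conversion constant of 0.056 ng/uU. Treated as a constant, not
#' re-derived.
#'
#' @format a single number, 0.056 (ng/uU).
#' @export
molar_csr_per_isr <- 0.056

#' Normalized root-sum-square error
#'
#' \eqn{\sqrt{\sum_k (z_k - \hat z_k)^2}} divided by the mean (trajectory
#' fits) or the maximum (CSR~ISR line fit) of the reference series. Note
#' there is no 1/N inside the root, so values are comparable only between
#' series of equal length; all comparisons made by this package (across
#' subjects on a common sampling grid, and within the outlier screen, which
#' evaluates every candidate on the full measurement grid) satisfy that.
#'
#' @param measured,modeled numeric series of equal length.
#' @param normalizer `"mean"` or `"max"` of the reference series.
#' @param reference series whose mean/max normalizes the error; defaults to
#'   `measured`.
#' @return dimensionless error `>= 0`; zero iff the series are identical.
#' @export
rms_error <- function(measured, modeled, normalizer = c("mean", "max"),
                      reference = measured) {
  normalizer <- match.arg(normalizer)
  if (length(measured) != length(modeled) || length(measured) < 1L) {
    stop("series must have equal length >= 1", call. = FALSE)
  }
  denom <- if (normalizer == "mean") mean(reference) else max(reference)
  if (!is.finite(denom) || denom <= 0) {
    stop("normalizer value must be positive", call. = FALSE)
  }
  sqrt(sum((measured - modeled)^2)) / denom
}

#' Linear CSR~ISR fit against the 1:1 molar expectation
#'
#' Ordinary least squares of CSR on ISR (intercept included), with the line
#' error normalized by the maximum CSR. Because the two secretion functionals
#' are inferred independently, a slope near [molar_csr_per_isr] (0.056
#' ng/uU) validates the pair of fits; systematic deviation above it reflects
#' first-pass hepatic insulin extraction (see [hepatic_absorption()]).
#'
#' @param isr,csr secretion-rate series evaluated at the same measurement
#'   times; length >= 3.
#' @return an object of class `csr_isr_fit` with `slope` (ng/uU),
#'   `intercept`, and `rms_csr_isr`.
#' @export
csr_isr_fit <- function(isr, csr) {
  if (length(isr) != length(csr) || length(isr) < 3L) {
    stop("isr and csr must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(isr) <= 1e-8 * max(abs(isr))) {
    stop("degenerate fit: ISR series is (numerically) constant", call. = FALSE)
  }
  fit <- stats::lm(csr ~ isr)
  cf <- stats::coef(fit)
  rms <- rms_error(csr, as.numeric(stats::fitted(fit)), normalizer = "max",
                   reference = csr)
  structure(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 rms_csr_isr = rms),
            class = "csr_isr_fit")
}

#' Hepatic first-pass extraction from the CSR~ISR slope
#'
#' The ISR inferred from peripheral insulin is the post-hepatic rate
#' \eqn{u_{inferred} = u_{pancreatic} (1 - \alpha_h)}, while c-peptide
#' escapes the liver, so in molar units the CSR~ISR slope equals
#' \eqn{1/(1 - \alpha_h)}. Inverting with the 0.056 ng/uU conversion gives
#' \eqn{\alpha_h = 1 - 0.056/\mathrm{slope}}, clipped to `[0, 1)`; a slope
#' below 0.056 (sub-molar) yields `alpha_h = 0` with `sub_molar = TRUE`.
#'
#' @param slope fitted CSR~ISR slope in ng/uU; must be `> 0`.
#' @return a list with `alpha_h` (fraction in `[0, 1)`) and `sub_molar`
#'   flag.
#' @examples
#' hepatic_absorption(0.112)$alpha_h  # 0.5
#' @export
hepatic_absorption <- function(slope) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope <= 0) {
    stop("'slope' must be a single finite positive number", call. = FALSE)
  }
  list(alpha_h = max(0, 1 - molar_csr_per_isr / slope),
       sub_molar = slope < molar_csr_per_isr)
}

#' Evaluate the fitted secretion rate at a reference glucose
#'
#' Applies each accepted solution's secretion functional to `g_ref` and
#' summarizes the ensemble as mean +- SD. A warning is emitted when `g_ref`
#' exceeds the subject's maximum measured glucose, since the functional is
#' then extrapolated beyond the glucose range expressed during the test.
#'
#' @param ensemble a [fit_ensemble()].
#' @param g_ref reference glucose (default 140 mg/dl, converted to the
#'   ensemble's glucose unit).
#' @param g_ref_unit unit of `g_ref`.
#' @return a list with `mean`, `sd`, and the per-solution `rates`.
#' @export
isr_at <- function(ensemble, g_ref = 140, g_ref_unit = "mg/dl") {
  stopifnot(inherits(ensemble, "fit_ensemble"))
  g <- convert_glucose(g_ref, g_ref_unit, ensemble$glucose_unit)
  if (g > ensemble$glucose_range[2L]) {
    warning("reference glucose ", g, " ", ensemble$glucose_unit,
            " exceeds the subject's maximum measured glucose (",
            ensemble$glucose_range[2L],
            "); the secretion functional is extrapolated", call. = FALSE)
  }
  P <- ensemble$params
  rates <- P[, "Km"] / (1 + exp(P[, "alpha"] * (P[, "C0"] - g)))
  list(mean = mean(rates), sd = stats::sd(rates), rates = unname(rates))
}

#' Empirical cumulative distribution function
#'
#' Right-continuous ECDF used to compare per-subject summaries (e.g. the
#' secretion rate at a reference glucose, or CSR~ISR slopes) across groups.
#' A thin wrapper around [stats::ecdf()].
#'
#' @param values non-empty numeric vector.
#' @return a step function `F(x)` with `F(max) = 1` and `F(x < min) = 0`.
#' @export
rate_ecdf <- function(values) {
  if (length(values) == 0L || anyNA(values)) {
    stop("'values' must be non-empty and NA-free", call. = FALSE)
  }
  stats::ecdf(values)
}

# Modeled ensemble-mean trajectory values at requested times, looked up on
# the ensemble's interpolation grid (nearest node).
.traj_at <- function(ensemble, times, what = c("plasma_mean", "secretion_mean")) {
  what <- match.arg(what)
  gt <- ensemble$traj$time
  idx <- vapply(times, function(t) which.min(abs(gt - t)), integer(1L))
  if (any(abs(gt[idx] - times) > ensemble$step / 2 + 1e-9)) {
    stop("requested times fall outside the fitted trajectory grid",
         call. = FALSE)
  }
  ensemble$traj[[what]][idx]
}

#' Goodness-of-fit report for one subject
#'
#' Gathers the three validation metrics for a fitted subject: normalized RMS
#' reconstruction errors of the insulin and c-peptide trajectories
#' (mean-normalized), and the CSR~ISR linear fit (slope, intercept,
#' max-normalized line error) computed from the ensemble-mean secretion
#' trajectories at the measurement times. Also reports the implied hepatic
#' extraction fraction and the ISR at a reference glucose (default 140
#' mg/dl).
#'
#' The report is evaluated against `rec`, which need not be the record the
#' ensembles were fitted to: the outlier screen exploits this to score a
#' reduced fit against the full measurement grid.
#'
#' @param rec the [ogtt_record()] to evaluate against.
#' @param fit_insulin,fit_cpeptide [fit_ensemble()] objects (either may be
#'   `NULL`, disabling the metrics that need it).
#' @param g_ref,g_ref_unit reference glucose for the ISR evaluation.
#' @param times measurement times at which to evaluate; defaults to all of
#'   `rec$times`.
#' @return an object of class `fit_report` with fields `rms_insulin`,
#'   `rms_cpeptide`, `rms_csr_isr`, `slope`, `intercept`, `alpha_h`,
#'   `sub_molar`, `isr_at_ref` (`NA` where not computable).
#' @export
fit_report <- function(rec, fit_insulin = NULL, fit_cpeptide = NULL,
                       g_ref = 140, g_ref_unit = "mg/dl", times = rec$times) {
  stopifnot(inherits(rec, "ogtt_record"))
  rep <- list(rms_insulin = NA_real_, rms_cpeptide = NA_real_,
              rms_csr_isr = NA_real_, slope = NA_real_, intercept = NA_real_,
              alpha_h = NA_real_, sub_molar = NA,
              isr_at_ref = NA_real_, isr_at_ref_sd = NA_real_,
              g_ref = g_ref, g_ref_unit = g_ref_unit,
              subject_id = rec$subject_id)
  traj_rms <- function(ens, species) {
    z <- rec[[species]]
    keep <- !is.na(z) & rec$times %in% times
    rms_error(z[keep], .traj_at(ens, rec$times[keep], "plasma_mean"),
              normalizer = "mean")
  }
  if (!is.null(fit_insulin)) {
    rep$rms_insulin <- traj_rms(fit_insulin, "insulin")
    ia <- isr_at(fit_insulin, g_ref, g_ref_unit)
    rep$isr_at_ref <- ia$mean
    rep$isr_at_ref_sd <- ia$sd
  }
  if (!is.null(fit_cpeptide)) rep$rms_cpeptide <- traj_rms(fit_cpeptide, "cpeptide")
  if (!is.null(fit_insulin) && !is.null(fit_cpeptide)) {
    both <- !is.na(rec$insulin) & !is.na(rec$cpeptide) & rec$times %in% times
    tk <- rec$times[both]
    cf <- tryCatch(
      csr_isr_fit(.traj_at(fit_insulin, tk, "secretion_mean"),
                  .traj_at(fit_cpeptide, tk, "secretion_mean")),
      error = function(e) NULL)  # degenerate (constant) ISR: leave NA
    if (!is.null(cf)) {
      rep$rms_csr_isr <- cf$rms_csr_isr
      rep$slope <- cf$slope
      rep$intercept <- cf$intercept
      if (is.finite(cf$slope) && cf$slope > 0) {
        ha <- hepatic_absorption(cf$slope)
        rep$alpha_h <- ha$alpha_h
        rep$sub_molar <- ha$sub_molar
      }
    }
  }
  structure(rep, class = "fit_report")
}

#' Serialize a fit report to JSON
#'
#' @param report a [fit_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path) {
  stopifnot(inherits(report, "fit_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report> ", x$subject_id, "\n", sep = "")
  cat(sprintf("  RMS insulin %.4g | c-peptide %.4g | CSR~ISR %.4g\n",
              x$rms_insulin, x$rms_cpeptide, x$rms_csr_isr))
  cat(sprintf("  CSR~ISR slope %.4g ng/uU (molar expectation %.3f), alpha_h %.3g\n",
              x$slope, molar_csr_per_isr, x$alpha_h))
  cat(sprintf("  ISR at %g %s: %.4g +- %.4g\n", x$g_ref, x$g_ref_unit,
              x$isr_at_ref, x$isr_at_ref_sd))
  invisible(x)
}
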