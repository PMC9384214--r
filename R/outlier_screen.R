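# Leave-one-timepoint-out screening for suspect OGTT measurements.

#' Screen one timepoint for outlier behaviour
#'
#' Fits the subject twice with identical seeds and configuration — once on
#' the full record and once with the candidate timepoint removed (glucose
#' knot plus the associated insulin and c-peptide values) — and compares the
#' three goodness-of-fit metrics. Both fits are evaluated on the *full*
#' original measurement grid, so the comparison involves equally many
#' residuals on each side: for the reduced fit, the insulin/c-peptide values
#' at the removed time act as held-out prediction residuals. A corrupted
#' glucose knot poisons the interpolant driving the full fit, while after
#' its removal the smoothly bridged interpolant predicts the held-out
#' measurements well — so genuine outliers improve all three metrics on
#' removal, whereas removing a sound point costs held-out accuracy.
#'
#' Endpoints cannot be screened (their removal would turn interpolation into
#' extrapolation), and the record must have both species measured so that
#' all three metrics are defined.
#'
#' @param rec an [ogtt_record()] with both insulin and c-peptide.
#' @param t interior measurement time to screen (min).
#' @param kind compartment model kind.
#' @param bounds a [param_bounds()] applied to both species, or a named
#'   list `list(insulin =, cpeptide =)`; defaults to the record-derived
#'   [screening_bounds()], which forbid glucose-insensitive (absorbing)
#'   secretion functionals.
#' @param n_starts random starts per fit (default 100; screening runs four
#'   ensembles per point, so a reduced ensemble keeps it tractable).
#' @param seed RNG seed shared by the with/without fits for comparability.
#' @param ... passed to [fit_subject()] (e.g. `Ts`, `step`).
#' @return an object of class `screen_result`: `timepoint`, `baseline` and
#'   `without_point` ([fit_report()]s), `deltas` (without - baseline per
#'   metric; negative = improvement), and `improved_all` (all three RMS
#'   metrics strictly decreased).
#' @export
screen_timepoint <- function(rec, t, kind = c("single", "two_compartment"),
                             bounds = NULL, n_starts = 100, seed = 1, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "ogtt_record"))
  n <- length(rec$times)
  if (!t %in% rec$times[-c(1L, n)]) {
    stop("t = ", t, " min must be an interior measurement time ",
         "(endpoints anchor the interpolant and cannot be screened)",
         call. = FALSE)
  }
  if (sum(!is.na(rec$insulin)) < 5L || sum(!is.na(rec$cpeptide)) < 5L) {
    stop("screening needs both insulin and c-peptide measured", call. = FALSE)
  }
  # A record corrupted badly enough may admit no interior optimum at all;
  # fall back to the boundary-tolerant ensemble so the (poor) baseline fit
  # is still representable and comparable.
  fit_fallback <- function(r, sp, sd) {
    b <- if (is.null(bounds)) screening_bounds(rec, sp, kind)
         else if (inherits(bounds, "param_bounds")) bounds
         else bounds[[sp]]
    tryCatch(
      fit_ensemble(r, species = sp, kind = kind, bounds = b,
                   n_starts = n_starts, seed = sd, cost_tol = 2, ...),
      error = function(e) {
        fit_ensemble(r, species = sp, kind = kind, bounds = b,
                     n_starts = n_starts, seed = sd, allow_boundary = TRUE,
                     cost_tol = 2, ...)
      })
  }
  reduced_rec <- drop_timepoint(rec, t)
  full <- list(insulin = fit_fallback(rec, "insulin", seed),
               cpeptide = fit_fallback(rec, "cpeptide", seed + 1L))
  reduced <- list(insulin = fit_fallback(reduced_rec, "insulin", seed),
                  cpeptide = fit_fallback(reduced_rec, "cpeptide", seed + 1L))
  baseline <- fit_report(rec, full$insulin, full$cpeptide)
  without <- fit_report(rec, reduced$insulin, reduced$cpeptide)
  metrics <- c("rms_insulin", "rms_cpeptide", "rms_csr_isr")
  deltas <- vapply(metrics, function(m) without[[m]] - baseline[[m]],
                   numeric(1L))
  structure(list(timepoint = t, baseline = baseline, without_point = without,
                 deltas = deltas,
                 improved_all = all(is.finite(deltas)) && all(deltas < 0)),
            class = "screen_result")
}

#' Screen every interior timepoint of a record
#'
#' Runs [screen_timepoint()] for each interior measurement time whose
#' removal leaves a valid record (at least 4 glucose knots and enough
#' measurements to fit), and returns the results sorted by aggregate
#' improvement (sum of the three metric deltas, most negative first).
#' Deterministic for a fixed seed.
#'
#' @inheritParams screen_timepoint
#' @return an object of class `screen_set`: a list of `screen_result`,
#'   sorted; convert with [as.data.frame()] for a per-timepoint table.
#' @export
screen_all <- function(rec, kind = c("single", "two_compartment"),
                       bounds = NULL, n_starts = 100, seed = 1, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "ogtt_record"))
  n <- length(rec$times)
  interior <- if (n > 2L) rec$times[-c(1L, n)] else numeric(0L)
  results <- list()
  for (t in interior) {
    res <- tryCatch(
      screen_timepoint(rec, t, kind = kind, bounds = bounds,
                       n_starts = n_starts, seed = seed, ...),
      error = function(e) NULL)
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  if (length(results) > 1L) {
    agg <- vapply(results, function(r) sum(r$deltas), numeric(1L))
    results <- results[order(agg)]
  }
  structure(results, class = "screen_set")
}

#' @export
as.data.frame.screen_set <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(timepoint = numeric(0L), rms_insulin = numeric(0L),
                      rms_cpeptide = numeric(0L), rms_csr_isr = numeric(0L),
                      rms_insulin_without = numeric(0L),
                      rms_cpeptide_without = numeric(0L),
                      rms_csr_isr_without = numeric(0L),
                      improved_all = logical(0L)))
  }
  do.call(rbind, lapply(unclass(x), function(r) {
    data.frame(timepoint = r$timepoint,
               rms_insulin = r$baseline$rms_insulin,
               rms_cpeptide = r$baseline$rms_cpeptide,
               rms_csr_isr = r$baseline$rms_csr_isr,
               rms_insulin_without = r$without_point$rms_insulin,
               rms_cpeptide_without = r$without_point$rms_cpeptide,
               rms_csr_isr_without = r$without_point$rms_csr_isr,
               improved_all = r$improved_all)
  }))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> timepoint ", x$timepoint, " min: ",
      if (x$improved_all) "all three metrics improve on removal (suspect)"
      else "removal does not improve all metrics", "\n", sep = "")
  m <- rbind(baseline = unlist(x$baseline[c("rms_insulin", "rms_cpeptide",
                                            "rms_csr_isr")]),
             without = unlist(x$without_point[c("rms_insulin", "rms_cpeptide",
                                                "rms_csr_isr")]))
  print(round(m, 4))
  invisible(x)
}
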