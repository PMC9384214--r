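# Sparse OGTT records and the dense interpolated glucose input.

#' Construct a sparse OGTT record
#'
#' Holds the sparse measurement series of one subject: sample times (min,
#' e.g. `{-10, 0, 20, 30, 60, 90, 120, 150, 180}`), plasma glucose, and
#' optionally insulin (uU/ml) and c-peptide (ng/ml). Insulin and c-peptide
#' entries may be `NA` (excluded from fitting); glucose may not, since it
#' drives the model, and at least 4 glucose points are required for cubic
#' interpolation.
#'
#' @param times sample times in minutes, strictly increasing.
#' @param glucose plasma glucose at `times`; finite, non-negative.
#' @param insulin,cpeptide optional concentration series (`NA` allowed).
#' @param subject_id label.
#' @param glucose_unit `"mg/dl"` (clinical default) or `"mg/L"`.
#' @return an object of class `ogtt_record`.
#' @export
ogtt_record <- function(times, glucose, insulin = NULL, cpeptide = NULL,
                        subject_id = "subject", glucose_unit = "mg/dl") {
  .check_glucose_unit(glucose_unit)
  times <- as.numeric(times)
  glucose <- as.numeric(glucose)
  n <- length(times)
  if (n != length(glucose)) stop("times and glucose lengths differ", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times))) stop("times must be finite", call. = FALSE)
  d <- diff(times)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L] + 1L
    stop("times must be strictly increasing (violated at row ", bad,
         ", time ", times[bad], ")", call. = FALSE)
  }
  if (anyNA(glucose) || any(!is.finite(glucose)) || any(glucose < 0)) {
    bad <- which(!is.finite(glucose) | glucose < 0)[1L]
    stop("glucose must be finite and >= 0 at every time (violated at row ",
         bad, ")", call. = FALSE)
  }
  if (n < 4L) stop("at least 4 glucose points are required (got ", n, ")",
                   call. = FALSE)
  chk <- function(x, nm) {
    if (is.null(x)) return(rep(NA_real_, n))
    x <- as.numeric(x)
    if (length(x) != n) stop(nm, " length differs from times", call. = FALSE)
    if (any(x < 0, na.rm = TRUE)) {
      stop(nm, " must be >= 0 (violated at row ", which(x < 0)[1L], ")",
           call. = FALSE)
    }
    x
  }
  structure(list(times = times, glucose = glucose,
                 insulin = chk(insulin, "insulin"),
                 cpeptide = chk(cpeptide, "cpeptide"),
                 subject_id = as.character(subject_id)[1L],
                 glucose_unit = glucose_unit),
            class = "ogtt_record")
}

#' Read an OGTT record from CSV
#'
#' Expects a comma-separated file with a header row and columns `time_min`,
#' `glucose`, `insulin`, `cpeptide`; insulin/c-peptide cells may be empty
#' (treated as missing and excluded from fitting).
#'
#' @param path file path.
#' @param glucose_unit unit of the glucose column (not auto-detected).
#' @param subject_id label; defaults to the file name.
#' @return an [ogtt_record()].
#' @export
read_ogtt <- function(path, glucose_unit = "mg/dl",
                      subject_id = sub("\\.csv$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "glucose")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("OGTT CSV is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ogtt_record(times = df$time_min, glucose = df$glucose,
              insulin = if ("insulin" %in% names(df)) df$insulin,
              cpeptide = if ("cpeptide" %in% names(df)) df$cpeptide,
              subject_id = subject_id, glucose_unit = glucose_unit)
}

#' Write an OGTT record to CSV
#'
#' Inverse of [read_ogtt()]: columns `time_min`, `glucose`, `insulin`,
#' `cpeptide`, missing entries as empty cells.
#'
#' @param rec an [ogtt_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ogtt <- function(rec, path) {
  stopifnot(inherits(rec, "ogtt_record"))
  df <- data.frame(time_min = rec$times, glucose = rec$glucose,
                   insulin = rec$insulin, cpeptide = rec$cpeptide)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Dense cubic-spline glucose input
#'
#' Builds the interpolated glucose trajectory used as the model input: a
#' cubic spline through every measured (time, glucose) pair, evaluated on a
#' uniform grid (default 1 min) covering the measured span. No extrapolation
#' beyond the first/last sample is performed. The default natural boundary
#' condition (zero second derivative at the ends) avoids overshoot at the
#' sparse ends of an OGTT; `"fmm"` is available as an alternative. Negative
#' interpolated values (possible with spline overshoot between knots) are
#' clipped to zero with a warning.
#'
#' @param rec an [ogtt_record()].
#' @param step grid step in minutes (default 1).
#' @param method spline end condition, `"natural"` (default) or `"fmm"`.
#' @return an object of class `glucose_input` with elements `grid_times`,
#'   `values`, `fun` (vectorized interpolant, clipped at 0), `span`, `step`,
#'   `glucose_unit`.
#' @export
interpolate_glucose <- function(rec, step = 1, method = c("natural", "fmm")) {
  stopifnot(inherits(rec, "ogtt_record"))
  method <- match.arg(method)
  if (!is.finite(step) || step <= 0) stop("'step' must be > 0", call. = FALSE)
  sf <- stats::splinefun(rec$times, rec$glucose, method = method)
  span <- range(rec$times)
  fun <- function(t) {
    if (any(t < span[1L] - 1e-9 | t > span[2L] + 1e-9)) {
      stop("glucose interpolant evaluated outside the measured span",
           call. = FALSE)
    }
    pmax(0, sf(t))
  }
  n <- floor((span[2L] - span[1L]) / step + 1e-9)
  grid <- span[1L] + step * (0:n)
  raw <- sf(grid)
  if (any(raw < 0)) {
    warning("interpolated glucose dips below 0 between knots; clipped at 0",
            call. = FALSE)
  }
  structure(list(grid_times = grid, values = pmax(0, raw), fun = fun,
                 span = span, step = step, glucose_unit = rec$glucose_unit),
            class = "glucose_input")
}

#' Remove one timepoint from a record
#'
#' Drops the glucose, insulin, and c-peptide entries at time `t`, leaving the
#' original record unchanged. Used by the outlier screen: with the knot
#' removed, the glucose interpolant bridges the gap smoothly.
#'
#' @param rec an [ogtt_record()].
#' @param t a time present in `rec$times`.
#' @return a new, shorter [ogtt_record()].
#' @export
drop_timepoint <- function(rec, t) {
  stopifnot(inherits(rec, "ogtt_record"))
  i <- which(rec$times == t)
  if (length(i) != 1L) {
    stop("time ", t, " min is not a measurement time of this record",
         call. = FALSE)
  }
  ogtt_record(rec$times[-i], rec$glucose[-i], rec$insulin[-i],
              rec$cpeptide[-i], rec$subject_id, rec$glucose_unit)
}

#' @export
print.ogtt_record <- function(x, ...) {
  cat("<ogtt_record> ", x$subject_id, ": ", length(x$times),
      " samples over [", x$times[1L], ", ", x$times[length(x$times)],
      "] min, glucose in ", x$glucose_unit, "\n", sep = "")
  cat("  insulin measured at ", sum(!is.na(x$insulin)),
      " times, c-peptide at ", sum(!is.na(x$cpeptide)), "\n", sep = "")
  invisible(x)
}
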