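#' Convert glucose concentrations between mg/dl and mg/L
#'
#' The package is unit-agnostic for glucose: the sigmoid midpoint `C0` and
#' inverse width `alpha` are always stored in units matching the glucose
#' column of the record they were fitted to. Clinical OGTT data are usually
#' reported in mg/dl while physiological parameter ranges are often quoted in
#' mg/L, so an explicit converter is provided (1 mg/dl = 10 mg/L).
#'
#' @param x numeric vector of glucose concentrations (or of `C0` values).
#' @param from,to `"mg/dl"` or `"mg/L"`.
#' @return `x` expressed in the `to` unit.
#' @examples
#' convert_glucose(100, "mg/dl", "mg/L")  # 1000
#' @export
convert_glucose <- function(x, from = c("mg/dl", "mg/L"), to = c("mg/L", "mg/dl")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  if (from == "mg/dl") x * 10 else x / 10
}

.check_glucose_unit <- function(unit) {
  if (!unit %in% c("mg/dl", "mg/L")) {
    stop("glucose_unit must be \"mg/dl\" or \"mg/L\", got \"", unit, "\"",
         call. = FALSE)
  }
  unit
}
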