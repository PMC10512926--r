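#' Round half away from zero
#'
#' Clinical tables round 0.05 up, unlike [round()]'s round-half-even. A tiny
#' epsilon guards against values like 0.4999999999 produced by binary
#' floating point for quantities that are exactly representable in decimal.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# stop() with the offending field named, so callers can grep the message
stop_invalid <- function(field, msg) {
  stop(sprintf("invalid input: %s %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (any(!is.finite(x) | x <= 0)) stop_invalid(field, "must be a positive finite number")
  invisible(x)
}

# "88.9 (74.4-103.4)" style formatting used by the report tables (en dash)
fmt_pct_ci <- function(est, lo, hi) {
  sprintf("%.1f (%.1f–%.1f)",
          round_half_up(est, 1), round_half_up(lo, 1), round_half_up(hi, 1))
}

#' Convert serum creatinine from mg/dL to \eqn{\mu}mol/L
#'
#' Convenience conversion at the I/O boundary; all internal computation uses
#' \eqn{\mu}mol/L.
#'
#' @param x creatinine in mg/dL.
#' @return creatinine in \eqn{\mu}mol/L (`x * 88.4`).
#' @export
scr_mgdl_to_umol <- function(x) x * 88.4
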