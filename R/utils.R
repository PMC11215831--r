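`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(..., call. = FALSE) stop(..., call. = call.)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad(sprintf("`%s` must be a single finite number", name))
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop_bad(sprintf("`%s` = %g out of range (%s%g, %g%s)", name, x,
                     if (strict_lower) "" else "[", lower, upper,
                     if (strict_upper) "" else "]"))
  invisible(x)
}

#' A regularly sampled derived series with its own clock
#'
#' Feature series produced by the pipeline stages (wavelet details, per-window
#' cepstrum coefficients, foreground/background ratios, averaged envelopes) all
#' carry an effective sampling rate and the time of their first sample, so that
#' downstream stages and alarms can be expressed in seconds of the original
#' recording.
#'
#' @param values numeric vector (may contain `NA` during warm-up).
#' @param rate effective sampling rate in Hz.
#' @param t0 time (s) of the first sample relative to record start.
#' @return An object of class `"feature_series"`.
#' @export
feature_series <- function(values, rate, t0 = 0) {
  check_scalar(rate, "rate", 0, strict_lower = TRUE)
  check_scalar(t0, "t0")
  structure(list(values = as.numeric(values), rate = rate, t0 = t0),
            class = "feature_series")
}

#' @export
length.feature_series <- function(x) length(x$values)

#' Sample times of a feature series
#' @param x a [feature_series()].
#' @return numeric vector of times (s), one per sample.
#' @export
fs_times <- function(x) {
  stopifnot(inherits(x, "feature_series"))
  x$t0 + (seq_along(x$values) - 1L) / x$rate
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d samples @ %.4g Hz, t0 = %.3g s, %d NA\n",
              length(x$values), x$rate, x$t0, sum(is.na(x$values))))
  invisible(x)
}
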