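#' Recursive-least-squares AR configuration
#'
#' Order 8 with forgetting factor 0.99 tracks the slowly varying
#' quasi-periodic structure of the detail signals; segments of 500 samples
#' with 75% overlap (hop 125) define the window clock that every later
#' stage inherits.
#'
#' @param order AR model order `n`.
#' @param lambda forgetting factor, in (0, 1]; 1 recovers recursive ordinary
#'   least squares.
#' @param delta scale of the initial inverse correlation matrix `P0 =
#'   delta * I`, in (0, 1).
#' @param seg_len segment length in samples.
#' @param seg_overlap segment overlap fraction.
#' @param residual_mode if `TRUE`, segments are represented by the prediction
#'   error instead of the one-step-ahead estimate.
#' @return An object of class `"rls_config"`.
#' @export
rls_config <- function(order = 8L, lambda = 0.99, delta = 0.01,
                       seg_len = 500L, seg_overlap = 0.75,
                       residual_mode = FALSE) {
  check_scalar(order, "order", 1)
  check_scalar(lambda, "lambda", 0, 1, strict_lower = TRUE)
  check_scalar(delta, "delta", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(seg_len, "seg_len", order + 1)
  check_scalar(seg_overlap, "seg_overlap", 0, 1, strict_upper = TRUE)
  structure(list(order = as.integer(order), lambda = lambda, delta = delta,
                 seg_len = as.integer(seg_len), seg_overlap = seg_overlap,
                 residual_mode = isTRUE(residual_mode)),
            class = "rls_config")
}

#' RLS estimation of one segment
#'
#' Runs the exponentially weighted RLS recursion (initialization `a0 = 0`,
#' `P0 = delta * I`) over the segment and returns the one-step-ahead
#' estimated signal together with the coefficient trajectory. The first
#' `order` samples of the estimate are copied from the input, where no
#' prediction history exists.
#'
#' @param segment numeric vector, longer than `config$order`.
#' @param config an [rls_config()].
#' @return List with `est` (same length as input), `coefficients` (final
#'   estimate, length `order`) and `trajectory` (length x order matrix).
#' @export
rls_estimate <- function(segment, config = rls_config()) {
  stopifnot(inherits(config, "rls_config"))
  if (!all(is.finite(segment))) stop_bad("non-finite input")
  r <- rls_core(segment, config$order, config$lambda, config$delta, TRUE)
  r$est <- as.numeric(r$est)
  r$coefficients <- as.numeric(r$coefficients)
  if (config$residual_mode) r$est <- segment - r$est
  r
}

seg_starts <- function(n, seg_len, hop) {
  if (n < seg_len) stop_bad("series shorter than one segment (", seg_len, " samples)")
  seq(1L, n - seg_len + 1L, by = hop)
}

#' RLS-estimate every segmented detail series
#'
#' Each of the 12 detail series is cut into `seg_len`-sample windows with
#' `seg_overlap` overlap (default hop 125 samples) and RLS runs per window
#' with fresh state, so windows are independent. Window count and per-window
#' length are preserved.
#'
#' @param bank a [detail_bank()].
#' @param config an [rls_config()].
#' @return List of class `"est_bank"`: `series` (per input series a
#'   `seg_len x n_windows` matrix of estimates), `window_t0` (window start
#'   times, s), `window_rate` (windows per second, `fs / hop`), `labels`,
#'   `fs`.
#' @export
estimate_bank <- function(bank, config = rls_config()) {
  stopifnot(inherits(bank, "detail_bank"), inherits(config, "rls_config"))
  hop <- as.integer(round(config$seg_len * (1 - config$seg_overlap)))
  if (hop < 1L) stop_bad("segment overlap too large: hop < 1 sample")
  series <- lapply(bank$series, function(s) {
    starts <- seg_starts(length(s$values), config$seg_len, hop)
    segs <- vapply(starts, function(i) s$values[i:(i + config$seg_len - 1L)],
                   numeric(config$seg_len))
    segs <- matrix(segs, nrow = config$seg_len)
    est <- rls_segments(segs, config$order, config$lambda, config$delta)
    if (config$residual_mode) est <- segs - est
    est
  })
  starts <- seg_starts(length(bank$series[[1]]$values), config$seg_len, hop)
  structure(list(series = series,
                 window_t0 = (starts - 1L) / bank$fs,
                 window_rate = bank$fs / hop,
                 labels = bank$labels, fs = bank$fs,
                 annotations = bank$annotations,
                 patient_id = bank$patient_id),
            class = "est_bank")
}

#' AR order-selection criteria
#'
#' Batch autoregressive fits of orders `1..max_order` (Burg method) with the
#' Akaike Information Criterion `AIC = N log(sigma2) + 2p` and Final
#' Prediction Error `FPE = sigma2 (N + p) / (N - p)`. Offered for
#' inspection; the pipeline default order stays 8.
#'
#' @param x numeric vector, much longer than `max_order`.
#' @param max_order largest order to fit.
#' @return `data.frame` with columns `order`, `sigma2`, `aic`, `fpe`.
#' @export
order_criteria <- function(x, max_order) {
  check_scalar(max_order, "max_order", 1)
  if (length(x) < 10L * max_order) stop_bad("signal too short for max_order")
  if (stats::sd(x) == 0) stop_bad("degenerate (constant) signal")
  N <- length(x)
  rows <- lapply(seq_len(max_order), function(p) {
    fit <- stats::ar(x, aic = FALSE, order.max = p, method = "burg",
                     demean = TRUE)
    s2 <- fit$var.pred
    data.frame(order = p, sigma2 = s2,
               aic = N * log(s2) + 2 * p,
               fpe = s2 * (N + p) / (N - p))
  })
  do.call(rbind, rows)
}
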