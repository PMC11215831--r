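#' Real cepstrum of a window
#'
#' Inverse DFT of the log magnitude spectrum, with the forward DFT carrying a
#' `1/N` normalization: `X(k) = (1/N) sum_n x(n) exp(-i 2 pi k n / N)` and
#' `C(n) = (1/N) sum_k log|X(k)| exp(+i 2 pi k n / N)`. `C(0)` is therefore
#' the mean of `log|X(k)|` over bins -- the log geometric mean of the
#' magnitude spectrum, which drops sharply when energy concentrates into few
#' harmonic bins (quasi-periodicity) and rises with broadband energy.
#'
#' Magnitudes are floored at `log_floor_rel * max|X|` before the log so that
#' near-empty bins stay finite; an all-zero window has no defined log
#' spectrum and is rejected.
#'
#' @param window numeric vector (not all zeros).
#' @param log_floor_rel relative spectral floor applied before the log.
#' @return Numeric vector of cepstrum coefficients, same length as `window`
#'   (`C(0)` first). The imaginary residue of the inverse transform is
#'   checked to be below 1e-10 of scale and discarded.
#' @export
real_cepstrum <- function(window, log_floor_rel = 1e-12) {
  N <- length(window)
  if (N < 1L || all(window == 0))
    stop_bad("all-zero window: log magnitude spectrum undefined")
  X <- fft(window) / N
  mag <- Mod(X)
  mag <- pmax(mag, log_floor_rel * max(mag))
  C <- fft(log(mag), inverse = TRUE) / N
  if (max(Mod(Im(C))) > 1e-10 * max(1, max(Mod(Re(C)))))
    stop_bad("cepstrum imaginary residue above tolerance")
  Re(C)
}

#' First cepstrum coefficient of every window of the estimate bank
#'
#' For each of the 12 RLS-estimated, segmented series the per-window real
#' cepstrum is computed and the first coefficient (index 0, the mean
#' log-magnitude) retained, giving 12 scalar time series on the window
#' clock (`fs / hop`, about 2.05 Hz at fs = 256). Windows that are entirely
#' zero have no defined cepstrum and yield `NA` (with a warning).
#'
#' @param est_bank an [estimate_bank()] result.
#' @param coeff_index quefrency index kept (default 0; index 1 selectable).
#' @param log_floor_rel relative spectral floor, as in [real_cepstrum()].
#' @return List of class `"ceps_bank"`: `series` (12 [feature_series()] on
#'   the window clock), `labels`, and clock metadata.
#' @export
first_coefficient_series <- function(est_bank, coeff_index = 0L,
                                     log_floor_rel = 1e-12) {
  stopifnot(inherits(est_bank, "est_bank"))
  check_scalar(coeff_index, "coeff_index", 0)
  series <- lapply(est_bank$series, function(m) {
    N <- nrow(m)
    zero <- apply(m, 2, function(w) all(w == 0))
    vals <- rep(NA_real_, ncol(m))
    if (any(!zero)) {
      X <- mvfft(m[, !zero, drop = FALSE]) / N
      mag <- Mod(X)
      mx <- apply(mag, 2, max)
      mag <- pmax(mag, rep(log_floor_rel * mx, each = N))
      lg <- log(mag)
      if (coeff_index == 0L) {
        vals[!zero] <- colMeans(lg)
      } else {
        w <- exp(2i * pi * (0:(N - 1)) * coeff_index / N)
        vals[!zero] <- Re(colSums(lg * w)) / N
      }
    }
    if (any(zero))
      warning(sum(zero), " all-zero window(s) skipped (NA) in cepstrum stage")
    feature_series(vals, rate = est_bank$window_rate,
                   t0 = est_bank$window_t0[1])
  })
  structure(list(series = series, labels = est_bank$labels,
                 window_rate = est_bank$window_rate,
                 annotations = est_bank$annotations,
                 patient_id = est_bank$patient_id),
            class = "ceps_bank")
}
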