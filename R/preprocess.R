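#' Preprocessing configuration
#'
#' Band and order of the linear-phase FIR band-pass, and the epoching
#' geometry. The 6--20 Hz band retains the harmonic-rich part of adult
#' seizure activity while rejecting slow drifts and line-frequency range;
#' order 220 keeps enough morphological detail for detection. Epoch windows
#' are always derived as `seconds x actual fs`.
#'
#' @param band passband `(low, high)` in Hz.
#' @param fir_order FIR order (even; the filter has `fir_order + 1` taps).
#' @param window_len_s epoch length (s).
#' @param overlap_frac epoch overlap fraction in `[0, 1)`.
#' @return An object of class `"preproc_config"`.
#' @export
preproc_config <- function(band = c(6, 20), fir_order = 220,
                           window_len_s = 5, overlap_frac = 0.8) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  check_scalar(fir_order, "fir_order", 2)
  if (fir_order %% 2 != 0) stop_bad("`fir_order` must be even (linear phase, integer delay)")
  check_scalar(window_len_s, "window_len_s", 0, strict_lower = TRUE)
  check_scalar(overlap_frac, "overlap_frac", 0, 1, strict_upper = TRUE)
  structure(list(band = as.numeric(band), fir_order = as.integer(fir_order),
                 window_len_s = window_len_s, overlap_frac = overlap_frac),
            class = "preproc_config")
}

#' Remove the least-squares linear trend
#'
#' Subtracts the best-fitting straight line, leaving a zero-mean signal with
#' zero regression slope.
#'
#' @param x numeric vector, length >= 2.
#' @return Detrended vector of the same length.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) stop_bad("need at least 2 samples to detrend")
  t <- seq_len(n) - (n + 1) / 2          # centered time: orthogonal to intercept
  slope <- sum(t * x) / sum(t * t)
  x - mean(x) - slope * t
}

#' Design a Hamming-window linear-phase FIR band-pass filter
#'
#' Windowed-sinc design: ideal band-pass impulse response truncated to
#' `order + 1` taps and tapered by a Hamming window, then normalized to unit
#' gain at the passband center. Linear phase with group delay `order/2`.
#'
#' @param fs sampling rate (Hz).
#' @param band `(low, high)` cutoffs in Hz, inside `(0, fs/2)`.
#' @param order even filter order.
#' @return Numeric vector of `order + 1` taps.
#' @export
fir_bandpass_design <- function(fs, band, order) {
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop_bad("band must satisfy 0 < low < high < fs/2")
  m <- order / 2
  k <- seq(-m, m)
  sinc <- function(f, k) ifelse(k == 0, 2 * f / fs, sin(2 * pi * f * k / fs) / (pi * k))
  h <- sinc(band[2], k) - sinc(band[1], k)
  w <- 0.54 + 0.46 * cos(pi * k / m)     # Hamming, centered
  h <- h * w
  f0 <- mean(band)
  gain <- Mod(sum(h * exp(-2i * pi * f0 * k / fs)))
  h / gain
}

#' Apply the band-pass filter with group-delay compensation
#'
#' Convolves with the FIR taps after reflecting `order/2` samples at each
#' edge, then drops the group delay so the output is time-aligned with, and
#' of equal length to, the input (zero-phase alignment).
#'
#' @param x numeric vector; @param fs sampling rate (Hz).
#' @param config a [preproc_config()].
#' @return Filtered vector, same length as `x`.
#' @export
bandpass_fir <- function(x, fs, config = preproc_config()) {
  stopifnot(inherits(config, "preproc_config"))
  n <- length(x)
  if (config$fir_order >= n) stop_bad("signal shorter than the filter order")
  h <- fir_bandpass_design(fs, config$band, config$fir_order)
  m <- config$fir_order / 2
  xp <- c(rev(x[2:(m + 1)]), x, rev(x[(n - m):(n - 1)]))
  y <- fft_convolve(xp, h)               # full convolution, length n + 4m
  y[(2 * m + 1):(2 * m + n)]
}

# linear convolution via zero-padded FFT (lengths here are ~3e5 x 221)
fft_convolve <- function(x, h) {
  nt <- length(x) + length(h) - 1L
  nf <- stats::nextn(nt, 2)
  y <- Re(fft(fft(c(x, numeric(nf - length(x)))) *
              fft(c(h, numeric(nf - length(h)))), inverse = TRUE)) / nf
  y[seq_len(nt)]
}

#' Cut a signal into overlapping epochs
#'
#' Windows of `round(window_len_s * fs)` samples with hop
#' `round(window_len_s * fs * (1 - overlap_frac))`; a trailing partial window
#' is dropped. Used for streaming delivery; the analysis stages operate on
#' the continuous filtered signal.
#'
#' @param x numeric vector; @param fs sampling rate (Hz).
#' @param config a [preproc_config()].
#' @return List with `epochs` (matrix, one column per epoch) and `start_s`
#'   (epoch start times in seconds).
#' @export
epoch_signal <- function(x, fs, config = preproc_config()) {
  w <- as.integer(round(config$window_len_s * fs))
  hop <- as.integer(round(w * (1 - config$overlap_frac)))
  if (hop < 1L) stop_bad("overlap too large: hop < 1 sample")
  if (length(x) < w) stop_bad("signal shorter than one window")
  starts <- seq(1L, length(x) - w + 1L, by = hop)
  list(epochs = vapply(starts, function(s) x[s:(s + w - 1L)], numeric(w)),
       start_s = (starts - 1L) / fs)
}

#' Preprocess both channels of a record
#'
#' Linear detrend followed by the band-pass filter, per channel; returns a
#' record with the same metadata.
#'
#' @param record an [eeg_record()].
#' @param config a [preproc_config()].
#' @return A preprocessed [eeg_record()].
#' @export
preprocess_record <- function(record, config = preproc_config()) {
  stopifnot(inherits(record, "eeg_record"))
  dat <- apply(record$data, 2, function(ch)
    bandpass_fir(detrend_linear(ch), record$fs, config))
  out <- eeg_record(dat, fs = record$fs, channel_labels = record$channel_labels,
                    annotations = record$annotations,
                    patient_id = record$patient_id)
  attr(out, "schedule") <- attr(record, "schedule")
  out
}
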