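#' Foreground/background morphology configuration
#'
#' Windows are denominated in seconds and converted to samples at the
#' effective rate of the series being processed (the cepstrum window clock,
#' about 2.05 Hz at fs = 256), with a floor of `min_window` samples per
#' median window. The background update stride `s_s` of 0.5 s and forgetting
#' factor 0.99 give a background memory of roughly a minute on that clock.
#'
#' @param q_s foreground median window (s).
#' @param q2_s background median window (s).
#' @param s_s background update stride (s).
#' @param lambda_bg background forgetting factor, in (0, 1).
#' @param min_window minimum median window, in samples.
#' @param warmup_s ratio samples within `warmup_s` seconds of the record
#'   start are emitted as `NA` and excluded from thresholding and voting.
#'   The default (60 s) covers the background's exponential memory horizon
#'   (about `1 / (1 - lambda_bg)` updates) plus the filter and RLS settling
#'   transients at the record edge.
#' @return An object of class `"morph_config"`.
#' @export
morph_config <- function(q_s = 1, q2_s = 1, s_s = 0.5, lambda_bg = 0.99,
                         min_window = 3L, warmup_s = 60) {
  check_scalar(q_s, "q_s", 0, strict_lower = TRUE)
  check_scalar(q2_s, "q2_s", 0, strict_lower = TRUE)
  check_scalar(s_s, "s_s", 0, strict_lower = TRUE)
  check_scalar(lambda_bg, "lambda_bg", 0, 1, strict_lower = TRUE,
               strict_upper = TRUE)
  check_scalar(min_window, "min_window", 1)
  check_scalar(warmup_s, "warmup_s", 0)
  structure(list(q_s = q_s, q2_s = q2_s, s_s = s_s, lambda_bg = lambda_bg,
                 min_window = as.integer(min_window), warmup_s = warmup_s),
            class = "morph_config")
}

to_samples <- function(seconds, rate, minimum = 1L)
  max(as.integer(minimum), as.integer(round(seconds * rate)))

# causal sliding median; shorter windows used for the first q-1 samples
sliding_median_causal <- function(x, q) {
  n <- length(x)
  out <- numeric(n)
  head_n <- min(q - 1L, n)
  for (k in seq_len(head_n))
    out[k] <- stats::median(x[1:k], na.rm = TRUE)
  if (n >= q) {
    emb <- stats::embed(x, q)   # row i = x[(i+q-1):(i)]
    out[q:n] <- apply(emb, 1, stats::median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Foreground series: causal median of the squared signal
#'
#' Squares the series (amplifying the interictal/seizure contrast and making
#' it sign-free), then applies a causal median filter of `q_s` seconds: the
#' foreground at sample `k` is the median of the last `q` squared samples.
#' The first `q - 1` samples use the available shorter window.
#'
#' @param series a [feature_series()].
#' @param config a [morph_config()].
#' @return A [feature_series()] on the same clock.
#' @export
foreground <- function(series, config = morph_config()) {
  stopifnot(inherits(series, "feature_series"), inherits(config, "morph_config"))
  if (length(series$values) == 0L) stop_bad("empty series")
  q <- to_samples(config$q_s, series$rate, config$min_window)
  feature_series(sliding_median_causal(series$values^2, q),
                 rate = series$rate, t0 = series$t0)
}

#' Background series: exponentially forgotten stride-sampled median
#'
#' At update instants spaced `s_s` seconds apart, the background is updated
#' as `BG = (1 - lambda) * median{FG_k, FG_(k-s), ..., FG_(k-(q2-1)s)} +
#' lambda * BG_prev`; between updates it holds its last value. The first
#' full median initializes the background; samples before the history fills
#' are `NA` (warm-up).
#'
#' @param fg_series the foreground [feature_series()].
#' @param config a [morph_config()].
#' @return A [feature_series()] on the same clock, `NA` during warm-up.
#' @export
background <- function(fg_series, config = morph_config()) {
  stopifnot(inherits(fg_series, "feature_series"), inherits(config, "morph_config"))
  fg <- fg_series$values
  n <- length(fg)
  q2 <- to_samples(config$q2_s, fg_series$rate, config$min_window)
  s <- to_samples(config$s_s, fg_series$rate, 1L)
  lam <- config$lambda_bg
  first <- (q2 - 1L) * s + 1L
  out <- rep(NA_real_, n)
  if (first > n) return(feature_series(out, fg_series$rate, fg_series$t0))
  bg <- stats::median(fg[seq(first, by = -s, length.out = q2)], na.rm = TRUE)
  out[first] <- bg
  if (first < n) for (k in (first + 1L):n) {
    if ((k - first) %% s == 0L) {
      med <- stats::median(fg[seq(k, by = -s, length.out = q2)], na.rm = TRUE)
      if (!is.na(med)) bg <- (1 - lam) * med + lam * bg
    }
    out[k] <- bg
  }
  feature_series(out, fg_series$rate, fg_series$t0)
}

#' Cross-channel foreground/background ratio bank
#'
#' For each wavelet level `l` two dimensionless ratios are formed, with the
#' numerator always the main channel's foreground:
#' `r(1) = FG(main, l) / BG(main, l)` (outputs 1..6) and
#' `r(2) = FG(main, l) / BG(contra, l)` (outputs 7..12). Near stationarity
#' the self-ratio hovers near 1; seizure-driven energy changes on the main
#' channel push both ratios up before the lagging background adapts.
#' Denominators below `eps` yield `NA` (logged via warning); warm-up
#' prefixes are `NA`.
#'
#' @param ceps_bank a [first_coefficient_series()] result (12 series:
#'   1..6 main, 7..12 contralateral).
#' @param config a [morph_config()].
#' @param eps denominator guard.
#' @return List of class `"ratio_bank"` with 12 [feature_series()] and
#'   `labels` of the form `r1_D<l>` / `r2_D<l>`.
#' @export
ratio_bank <- function(ceps_bank, config = morph_config(), eps = 1e-12) {
  stopifnot(inherits(ceps_bank, "ceps_bank"))
  ns <- length(ceps_bank$series)
  if (ns %% 2L != 0L) stop_bad("expected an even number of series (two channels)")
  levels <- ns %/% 2L
  lens <- vapply(ceps_bank$series, function(s) length(s$values), integer(1))
  if (length(unique(lens)) != 1L) stop_bad("misaligned series lengths")
  fg <- lapply(ceps_bank$series, foreground, config = config)
  bg <- lapply(fg, background, config = config)
  divide <- function(num, den) {
    v <- num$values / den$values
    low <- !is.na(den$values) & den$values < eps
    if (any(low)) {
      v[low] <- NA_real_
      warning(sum(low), " ratio sample(s) with near-zero background set to NA")
    }
    feature_series(v, num$rate, num$t0)
  }
  r1 <- lapply(seq_len(levels), function(l) divide(fg[[l]], bg[[l]]))
  r2 <- lapply(seq_len(levels), function(l) divide(fg[[l]], bg[[l + levels]]))
  if (config$warmup_s > 0) {
    r1 <- lapply(r1, mask_warmup, warmup_s = config$warmup_s)
    r2 <- lapply(r2, mask_warmup, warmup_s = config$warmup_s)
  }
  structure(list(series = c(r1, r2),
                 labels = c(paste0("r1_D", seq_len(levels)),
                            paste0("r2_D", seq_len(levels))),
                 annotations = ceps_bank$annotations,
                 patient_id = ceps_bank$patient_id),
            class = "ratio_bank")
}

mask_warmup <- function(series, warmup_s) {
  v <- series$values
  v[fs_times(series) < warmup_s] <- NA_real_
  feature_series(v, series$rate, series$t0)
}
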