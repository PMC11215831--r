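# Daubechies-4 (8-tap, 4 vanishing moments) scaling filter; sums to sqrt(2),
# unit l2 norm, double-shift orthogonal -- asserted in the test suite.
DB4_SCALING <- c(0.230377813308855230, 0.714846570552541500,
                 0.630880767929590400, -0.027983769416983850,
                 -0.187034811718881140, 0.030841381835986965,
                 0.032883011666982945, -0.010597401784997278)

qmf_highpass <- function(g) {
  L <- length(g)
  (-1)^(0:(L - 1)) * rev(g)
}

# one periodized analysis step: x (even length) -> (approx, detail)
dwt_step <- function(x, g = DB4_SCALING) {
  n <- length(x)
  h <- qmf_highpass(g)
  n2 <- n %/% 2L
  a <- numeric(n2); d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(g)) {
    idx <- (base + (m - 1L)) %% n + 1L
    a <- a + g[m] * x[idx]
    d <- d + h[m] * x[idx]
  }
  list(a = a, d = d)
}

# adjoint (= inverse, by orthogonality) of dwt_step
idwt_step <- function(a, d, g = DB4_SCALING) {
  n2 <- length(a)
  n <- 2L * n2
  h <- qmf_highpass(g)
  y <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(g)) {
    idx <- (base + (m - 1L)) %% n + 1L
    y[idx] <- y[idx] + g[m] * a + h[m] * d
  }
  y
}

# pad with reflected tail so length is a multiple of 2^levels and the
# coarsest level keeps >= 2 filter lengths (keeps the periodized transform
# exactly orthogonal)
dwt_pad <- function(x, levels) {
  n <- length(x)
  block <- 2L^levels
  target <- max(ceiling(n / block) * block, 2L * length(DB4_SCALING) * block)
  pad <- target - n
  while (pad > 0L) {
    take <- min(pad, n)
    x <- c(x, rev(x)[seq_len(take)])
    pad <- pad - take
  }
  x
}

#' Multilevel db4 detail decomposition of one channel
#'
#' Computes a 6-level (by default) orthogonal Daubechies-4 discrete wavelet
#' transform with periodized boundary handling, then reconstructs each
#' level's detail signal back to the input length by the single-branch
#' inverse transform (that level's coefficients kept, all others zeroed).
#' Every detail series therefore shares the original time base, and the six
#' detail reconstructions plus the level-6 approximation reconstruction sum
#' to the input exactly (orthogonal perfect reconstruction).
#'
#' At `fs = 256` Hz the detail bands are roughly D1 64--128, D2 32--64,
#' D3 16--32, D4 8--16, D5 4--8, D6 2--4 Hz.
#'
#' @param x numeric vector, length at least `2^levels`.
#' @param fs sampling rate (Hz), carried on the output series.
#' @param wavelet_name only `"db4"` is provided.
#' @param levels decomposition depth (default 6).
#' @return List of class `"detail_decomp"`: `details` (list of `levels`
#'   full-length [feature_series()]), `approx` (the coarse reconstruction),
#'   `coeffs` (decimated detail coefficient vectors, for inspection),
#'   `fs`, `levels`.
#' @export
dwt_details <- function(x, fs, wavelet_name = "db4", levels = 6L) {
  if (!identical(wavelet_name, "db4"))
    stop_bad("only the db4 wavelet is provided")
  check_scalar(levels, "levels", 1)
  n <- length(x)
  if (n < 2L^levels) stop_bad("signal too short for ", levels, " levels")
  xp <- dwt_pad(x, levels)
  cD <- vector("list", levels)
  a <- xp
  for (j in seq_len(levels)) {
    st <- dwt_step(a)
    cD[[j]] <- st$d
    a <- st$a
  }
  recon <- function(cd_level, coef) {
    up <- coef
    if (cd_level > 0L)
      up <- idwt_step(numeric(length(coef)), coef)
    for (lev in seq_len(if (cd_level > 0L) cd_level - 1L else levels))
      up <- idwt_step(up, numeric(length(up)))
    up[seq_len(n)]
  }
  details <- lapply(seq_len(levels), function(j)
    feature_series(recon(j, cD[[j]]), rate = fs))
  approx <- feature_series(recon(0L, a), rate = fs)
  structure(list(details = details, approx = approx, coeffs = cD,
                 fs = fs, levels = levels, wavelet_name = wavelet_name),
            class = "detail_decomp")
}

#' Detail bank of a preprocessed two-channel record
#'
#' Applies [dwt_details()] to both channels and returns the 12 detail series
#' in the fixed order main D1..D6, contralateral D1..D6. This ordering is
#' load-bearing: downstream outputs 1..6 compare the main channel with
#' itself, outputs 7..12 compare it with the contralateral channel, and the
#' trained thresholds are indexed accordingly.
#'
#' @param record a preprocessed [eeg_record()] with two channels.
#' @param wavelet_name,levels passed to [dwt_details()].
#' @return List of class `"detail_bank"`: `series` (12 [feature_series()]),
#'   `labels`, `fs`, `levels`.
#' @export
detail_bank <- function(record, wavelet_name = "db4", levels = 6L) {
  stopifnot(inherits(record, "eeg_record"))
  if (ncol(record$data) != 2L) stop_bad("record must have exactly two channels")
  per_ch <- lapply(1:2, function(j)
    dwt_details(record$data[, j], record$fs, wavelet_name, levels))
  series <- c(per_ch[[1]]$details, per_ch[[2]]$details)
  labels <- c(paste0("main_D", seq_len(levels)),
              paste0("contra_D", seq_len(levels)))
  structure(list(series = series, labels = labels, fs = record$fs,
                 levels = levels, wavelet_name = wavelet_name,
                 annotations = record$annotations,
                 patient_id = record$patient_id),
            class = "detail_bank")
}
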