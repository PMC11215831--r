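#' Envelope-preparation configuration
#'
#' The averaging window (2 s, 1 s overlap) removes bursts and
#' down-samples; the positive envelope interpolates through local maxima at
#' least `peak_min_separation` samples apart so a single threshold can
#' separate the interictal baseline from the IT rise.
#'
#' @param avg_window_s averaging window (s).
#' @param avg_overlap_s averaging overlap (s), below `avg_window_s`.
#' @param peak_min_separation minimum distance between envelope peaks, in
#'   samples of the averaged series.
#' @return An object of class `"envelope_config"`.
#' @export
envelope_config <- function(avg_window_s = 2, avg_overlap_s = 1,
                            peak_min_separation = 30L) {
  check_scalar(avg_window_s, "avg_window_s", 0, strict_lower = TRUE)
  check_scalar(avg_overlap_s, "avg_overlap_s", 0)
  if (avg_overlap_s >= avg_window_s)
    stop_bad("`avg_overlap_s` must be below `avg_window_s`")
  check_scalar(peak_min_separation, "peak_min_separation", 1)
  structure(list(avg_window_s = avg_window_s, avg_overlap_s = avg_overlap_s,
                 peak_min_separation = as.integer(peak_min_separation)),
            class = "envelope_config")
}

#' Windowed moving average with down-sampling
#'
#' Window means with hop `window - overlap` (in samples of the series
#' clock). Windows containing `NA` are excluded (emitted as `NA`).
#'
#' @param series a [feature_series()].
#' @param config an [envelope_config()].
#' @return A [feature_series()] at rate `rate / hop`.
#' @export
moving_average <- function(series, config = envelope_config()) {
  stopifnot(inherits(series, "feature_series"), inherits(config, "envelope_config"))
  x <- series$values
  if (length(x) == 0L) stop_bad("empty series")
  w <- to_samples(config$avg_window_s, series$rate, 1L)
  hop <- max(1L, to_samples(config$avg_window_s - config$avg_overlap_s,
                            series$rate, 1L))
  if (length(x) < w) stop_bad("series shorter than the averaging window")
  starts <- seq(1L, length(x) - w + 1L, by = hop)
  vals <- vapply(starts, function(i) {
    win <- x[i:(i + w - 1L)]
    if (anyNA(win)) NA_real_ else mean(win)
  }, numeric(1))
  feature_series(vals, rate = series$rate / hop,
                 t0 = series$t0 + (starts[1] - 1L) / series$rate)
}

# local maxima indices (plateau-tolerant), then greedy enforcement of the
# minimum separation keeping taller peaks first
find_peaks <- function(x, min_sep) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(cand) < 2L) return(cand)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand)
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  sort(keep)
}

#' Positive envelope of a series
#'
#' Finds local maxima separated by at least `peak_min_separation` samples and
#' interpolates a shape-preserving (monotone Hermite) piecewise cubic through
#' them, evaluated at every sample; before the first and after the last peak
#' the envelope is held at that peak's value. With fewer than two peaks the
#' series itself is returned with a warning. Leading/trailing `NA` (warm-up)
#' samples are preserved as `NA`.
#'
#' @param series a [feature_series()].
#' @param config an [envelope_config()].
#' @return A [feature_series()] on the same clock.
#' @export
positive_envelope <- function(series, config = envelope_config()) {
  stopifnot(inherits(series, "feature_series"), inherits(config, "envelope_config"))
  x <- series$values
  ok <- which(!is.na(x))
  out <- rep(NA_real_, length(x))
  if (length(ok) >= 3L) {
    seg <- x[ok[1]:ok[length(ok)]]
    pk <- find_peaks(seg, config$peak_min_separation)
    if (length(pk) >= 2L) {
      f <- stats::splinefun(pk, seg[pk], method = "monoH.FC")
      idx <- seq_along(seg)
      env <- f(pmin(pmax(idx, pk[1]), pk[length(pk)]))
      out[ok[1]:ok[length(ok)]] <- env
    } else {
      warning("fewer than 2 peaks found; envelope falls back to the series itself")
      out[ok[1]:ok[length(ok)]] <- seg
    }
  } else if (length(ok)) {
    warning("fewer than 2 peaks found; envelope falls back to the series itself")
    out[ok] <- x[ok]
  }
  feature_series(out, series$rate, series$t0)
}

#' Threshold-training configuration
#'
#' @param sop_s Seizure Occurrence Period: the fixed window length (s)
#'   within which an alarm counts as a prediction of a seizure in it.
#' @param n_grid number of quantile-spaced candidate thresholds swept over
#'   the interictal value range of each output.
#' @param sustain_s minimum time (s) an output must stay above threshold to
#'   count as a crossing (default 0: a single sample suffices).
#' @return An object of class `"threshold_config"`.
#' @export
threshold_config <- function(sop_s = 100, n_grid = 200L, sustain_s = 0) {
  check_scalar(sop_s, "sop_s", 0, strict_lower = TRUE)
  check_scalar(n_grid, "n_grid", 2)
  check_scalar(sustain_s, "sustain_s", 0)
  structure(list(sop_s = sop_s, n_grid = as.integer(n_grid),
                 sustain_s = sustain_s),
            class = "threshold_config")
}

# SOP window grid over [t0, t_end): anchored so that a boundary coincides
# with the ictal onset when one is annotated, keeping "prediction before
# onset" well-defined
sop_grid <- function(t0, t_end, sop_s, ictal_onset = NA_real_) {
  anchor <- if (is.na(ictal_onset)) t0 else
    ictal_onset - sop_s * ceiling((ictal_onset - t0) / sop_s)
  starts <- seq(anchor, t_end, by = sop_s)
  starts <- starts[starts + sop_s > t0 & starts < t_end]
  data.frame(start = starts, end = starts + sop_s)
}

# first time env > thr sustained for sustain_s, restricted to [from, to); NA
# if never
first_crossing <- function(env, thr, from = -Inf, to = Inf, sustain_s = 0) {
  t <- fs_times(env)
  above <- !is.na(env$values) & env$values > thr & t >= from & t < to
  if (!any(above)) return(NA_real_)
  if (sustain_s <= 0) return(t[which(above)[1]])
  need <- max(1L, as.integer(ceiling(sustain_s * env$rate)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit)) return(NA_real_)
  t[ends[hit[1]] - r$lengths[hit[1]] + 1L]
}

#' Train patient-specific thresholds on envelope outputs
#'
#' For each of the 12 envelope outputs, candidate thresholds are swept over a
#' quantile-spaced grid of the output's interictal values (plus the
#' interictal maximum). A candidate is feasible when it produces zero
#' interictal crossings on all training records; among feasible candidates
#' the one detecting the most IT periods inside their SOP windows is chosen,
#' tie-broken by the earliest mean detection latency. Outputs with no
#' feasible detecting threshold are rejected. At least one output must be
#' accepted for a usable model.
#'
#' @param env_banks list of training envelope banks (each a list of 12
#'   [feature_series()] via the `series` element) with `annotations`;
#'   interictal-only records may be included.
#' @param config a [threshold_config()].
#' @param envelope list of configs echoed into the model (optional).
#' @return An object of class `"it_model"`; see [it_fit()] for the
#'   high-level interface.
#' @export
train_thresholds <- function(env_banks, config = threshold_config(),
                             envelope = NULL) {
  stopifnot(length(env_banks) >= 1L)
  n_out <- length(env_banks[[1]]$series)
  has_it <- vapply(env_banks, function(b)
    !is.na(annotation_time_df(b$annotations, "it_onset")), logical(1))
  if (!any(has_it))
    stop_bad("no training record contains an annotated IT onset")

  thresholds <- rep(NA_real_, n_out)
  latencies <- rep(NA_real_, n_out)
  for (j in seq_len(n_out)) {
    inter_vals <- numeric(0)
    for (b in env_banks) {
      env <- b$series[[j]]
      it_on <- annotation_time_df(b$annotations, "it_onset")
      t <- fs_times(env)
      lim <- if (is.na(it_on)) Inf else it_on
      v <- env$values[t < lim & !is.na(env$values)]
      inter_vals <- c(inter_vals, v)
    }
    if (!length(inter_vals)) next
    grid <- unique(c(stats::quantile(inter_vals,
                                     probs = seq(0, 1, length.out = config$n_grid),
                                     names = FALSE, type = 7),
                     max(inter_vals)))
    best <- NULL
    for (thr in sort(grid)) {
      fp <- FALSE; ndet <- 0L; lat <- numeric(0)
      for (b in env_banks) {
        env <- b$series[[j]]
        it_on <- annotation_time_df(b$annotations, "it_onset")
        ict_on <- annotation_time_df(b$annotations, "ictal_onset")
        lim <- if (is.na(it_on)) Inf else it_on
        if (!is.na(first_crossing(env, thr, to = lim,
                                  sustain_s = config$sustain_s))) {
          fp <- TRUE; break
        }
        if (!is.na(it_on)) {
          sop_end <- if (is.na(ict_on)) it_on + config$sop_s else ict_on
          cross <- first_crossing(env, thr, from = sop_end - config$sop_s,
                                  to = sop_end, sustain_s = config$sustain_s)
          if (!is.na(cross)) { ndet <- ndet + 1L; lat <- c(lat, cross - it_on) }
        }
      }
      if (fp || ndet == 0L) next
      cand <- list(thr = thr, ndet = ndet, lat = mean(lat))
      if (is.null(best) || cand$ndet > best$ndet ||
          (cand$ndet == best$ndet && cand$lat < best$lat))
        best <- cand
    }
    if (!is.null(best)) {
      thresholds[j] <- best$thr
      latencies[j] <- best$lat
    }
  }
  K <- sum(!is.na(thresholds))
  if (K == 0L)
    stop_bad("training failure: no output admits a zero-error detecting threshold")
  structure(list(thresholds = thresholds,
                 accepted = !is.na(thresholds),
                 K = K, quorum = as.integer(ceiling(K / 2)),
                 sop_s = config$sop_s, sustain_s = config$sustain_s,
                 train_latency_s = latencies,
                 labels = env_banks[[1]]$labels %||% paste0("out", seq_len(n_out)),
                 patient_id = env_banks[[1]]$patient_id %||% "unknown",
                 config = list(threshold = config, envelope = envelope)),
            class = "it_model")
}

annotation_time_df <- function(ann, label) {
  if (is.null(ann) || !nrow(ann)) return(NA_real_)
  t <- ann$time_s[ann$label == label]
  if (length(t)) t[1] else NA_real_
}

#' Vote-based prediction on a test envelope bank
#'
#' The record is partitioned into SOP windows (grid anchored at the ictal
#' onset annotation when present). Within a window an accepted output
#' "fires" when its envelope exceeds its threshold; the window is flagged IT
#' when at least `quorum` (= `ceil(K/2)`) outputs fire, and the alarm time
#' is the earliest instant at which the quorum is met (the quorum-th
#' smallest first-crossing time).
#'
#' @param env_bank an envelope bank (list with 12 `series`, `annotations`).
#' @param model an `"it_model"` from [train_thresholds()] / [it_fit()].
#' @return An object of class `"it_prediction"`: `windows` data.frame
#'   (`start`, `end`, `votes`, `flagged`, `alarm_time`), `alarm_times`,
#'   per-output `crossing_times`.
#' @export
predict_alarms <- function(env_bank, model) {
  stopifnot(inherits(model, "it_model"))
  if (is.null(model$K) || model$K < 1L)
    stop_bad("model has no accepted outputs and cannot predict")
  if (length(env_bank$series) != length(model$thresholds))
    stop_bad("envelope/model output-index mismatch")
  env1 <- env_bank$series[[1]]
  t_all <- fs_times(env1)
  t_end <- max(t_all) + 1 / env1$rate
  ict_on <- annotation_time_df(env_bank$annotations, "ictal_onset")
  grid <- sop_grid(min(t_all), t_end, model$sop_s, ict_on)
  acc <- which(model$accepted)
  grid$votes <- 0L
  grid$alarm_time <- NA_real_
  crossing_times <- vector("list", length(env_bank$series))
  for (w in seq_len(nrow(grid))) {
    firsts <- rep(NA_real_, length(acc))
    for (i in seq_along(acc)) {
      j <- acc[i]
      firsts[i] <- first_crossing(env_bank$series[[j]], model$thresholds[j],
                                  from = grid$start[w], to = grid$end[w],
                                  sustain_s = model$sustain_s)
    }
    fired <- which(!is.na(firsts))
    grid$votes[w] <- length(fired)
    if (length(fired) >= model$quorum)
      grid$alarm_time[w] <- sort(firsts[fired])[model$quorum]
    for (i in fired)
      crossing_times[[acc[i]]] <- c(crossing_times[[acc[i]]], firsts[i])
  }
  grid$flagged <- grid$votes >= model$quorum
  structure(list(windows = grid,
                 alarm_times = grid$alarm_time[grid$flagged],
                 crossing_times = crossing_times,
                 sop_s = model$sop_s,
                 annotations = env_bank$annotations,
                 patient_id = env_bank$patient_id %||% "unknown"),
            class = "it_prediction")
}

#' @export
print.it_prediction <- function(x, ...) {
  cat(sprintf("<it_prediction> patient %s: %d SOP windows (%g s), %d flagged\n",
              x$patient_id, nrow(x$windows), x$sop_s, sum(x$windows$flagged)))
  if (length(x$alarm_times))
    cat("  alarms at:", paste(sprintf("%.1f s", x$alarm_times), collapse = ", "), "\n")
  invisible(x)
}
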