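#' Full pipeline configuration
#'
#' Bundles the per-stage configurations. Unknown arguments are rejected.
#'
#' @param preproc a [preproc_config()].
#' @param wavelet list with `name` (only `"db4"`) and `levels`.
#' @param ar an [rls_config()].
#' @param cepstrum list with `coeff_index` and `log_floor_rel`.
#' @param morph a [morph_config()].
#' @param envelope an [envelope_config()].
#' @param threshold a [threshold_config()].
#' @return An object of class `"it_config"`.
#' @export
it_config <- function(preproc = preproc_config(),
                      wavelet = list(name = "db4", levels = 6L),
                      ar = rls_config(),
                      cepstrum = list(coeff_index = 0L, log_floor_rel = 1e-12),
                      morph = morph_config(),
                      envelope = envelope_config(),
                      threshold = threshold_config()) {
  stopifnot(inherits(preproc, "preproc_config"), inherits(ar, "rls_config"),
            inherits(morph, "morph_config"),
            inherits(envelope, "envelope_config"),
            inherits(threshold, "threshold_config"))
  if (!setequal(names(wavelet), c("name", "levels")))
    stop_bad("`wavelet` must have exactly the keys `name`, `levels`")
  if (!setequal(names(cepstrum), c("coeff_index", "log_floor_rel")))
    stop_bad("`cepstrum` must have exactly the keys `coeff_index`, `log_floor_rel`")
  structure(list(preproc = preproc, wavelet = wavelet, ar = ar,
                 cepstrum = cepstrum, morph = morph, envelope = envelope,
                 threshold = threshold),
            class = "it_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [it_config()]; each section holds
#' the arguments of the corresponding `*_config()` constructor. Missing
#' sections take defaults; unknown keys are rejected by the constructors.
#'
#' @param path a `.yaml`/`.yml` (requires the yaml package) or `.json` file.
#' @return An [it_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_bad("reading YAML requires the `yaml` package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("preproc", "wavelet", "ar", "cepstrum", "morph", "envelope",
             "threshold")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop_bad("unknown config section(s): ",
                              paste(extra, collapse = ", "))
  args <- list()
  build <- function(section, fun) {
    if (is.null(raw[[section]])) return(NULL)
    do.call(fun, as.list(raw[[section]]))
  }
  args$preproc <- build("preproc", preproc_config)
  args$ar <- build("ar", rls_config)
  args$morph <- build("morph", morph_config)
  args$envelope <- build("envelope", envelope_config)
  args$threshold <- build("threshold", threshold_config)
  for (sec in c("wavelet", "cepstrum"))
    if (!is.null(raw[[sec]])) args[[sec]] <- as.list(raw[[sec]])
  do.call(it_config, args[!vapply(args, is.null, logical(1))])
}

#' Run the feature pipeline on one record
#'
#' Executes preprocessing, the db4 detail decomposition, windowed RLS
#' estimation, the first-cepstrum-coefficient series, the
#' foreground/background ratio bank, averaging, and the positive envelope,
#' returning the 12 envelope series (plus intermediate stages on request).
#'
#' @param record an [eeg_record()] with two channels.
#' @param config an [it_config()].
#' @param keep_stages if `TRUE`, all intermediate stage outputs are attached
#'   (`det`, `est`, `ceps`, `rat`, `ave`).
#' @return List of class `"envelope_bank"`: `series` (12 envelope
#'   [feature_series()]), `labels`, `annotations`, `patient_id`; with
#'   `stages` when requested.
#' @export
pipeline_features <- function(record, config = it_config(),
                              keep_stages = FALSE) {
  stopifnot(inherits(record, "eeg_record"), inherits(config, "it_config"))
  pre <- preprocess_record(record, config$preproc)
  det <- detail_bank(pre, config$wavelet$name, config$wavelet$levels)
  est <- estimate_bank(det, config$ar)
  ceps <- first_coefficient_series(est, config$cepstrum$coeff_index,
                                   config$cepstrum$log_floor_rel)
  rat <- ratio_bank(ceps, config$morph)
  ave <- lapply(rat$series, moving_average, config = config$envelope)
  env <- lapply(ave, positive_envelope, config = config$envelope)
  out <- structure(list(series = env, labels = rat$labels,
                        annotations = record$annotations,
                        patient_id = record$patient_id),
                   class = "envelope_bank")
  if (keep_stages)
    out$stages <- list(det = det, est = est, ceps = ceps, rat = rat, ave = ave)
  out
}

#' Fit a patient-specific Intervention-Time prediction model
#'
#' The central fitting function: runs the feature pipeline on each training
#' record and learns one accepted-or-rejected threshold per envelope output
#' ([train_thresholds()]). At least one record must carry an annotated IT
#' onset; additional interictal-only records tighten the thresholds.
#'
#' @param records a single [eeg_record()] or a list of them.
#' @param config an [it_config()].
#' @return An object of class `"it_model"` with components `thresholds`
#'   (length 12, `NA` = rejected), `accepted`, `K`, `quorum`, `sop_s`,
#'   plus the training envelopes (for [plot.it_model()]) and the
#'   configuration. Methods: [print.it_model()], [summary.it_model()],
#'   [coef.it_model()], [predict.it_model()], [plot.it_model()].
#' @examples
#' \donttest{
#' p <- seizure_model_params(seed = 1)
#' sch <- default_schedule(t_it = 200, t_ictal = 230, t_end = 300)
#' m <- it_fit(generate_record(p, sch))
#' m
#' }
#' @export
it_fit <- function(records, config = it_config()) {
  if (inherits(records, "eeg_record")) records <- list(records)
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "eeg_record")))
  banks <- lapply(records, pipeline_features, config = config)
  model <- train_thresholds(banks, config$threshold, config$envelope)
  model$config <- config
  model$train_envelopes <- banks
  model$n_train <- length(records)
  model
}

#' @export
print.it_model <- function(x, ...) {
  cat(sprintf("<it_model> patient %s: %d/%d outputs accepted, quorum %d, SOP %g s\n",
              x$patient_id, x$K, length(x$thresholds), x$quorum, x$sop_s))
  acc <- which(x$accepted)
  if (length(acc))
    cat("  thresholds:",
        paste(sprintf("%s=%.3g", x$labels[acc], x$thresholds[acc]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted IT prediction model
#'
#' @param object an `"it_model"`.
#' @param ... unused.
#' @return `data.frame` with one row per output: `label`, `accepted`,
#'   `threshold`, `train_latency_s`.
#' @export
summary.it_model <- function(object, ...) {
  df <- data.frame(label = object$labels,
                   accepted = object$accepted,
                   threshold = object$thresholds,
                   train_latency_s = object$train_latency_s)
  class(df) <- c("summary.it_model", "data.frame")
  df
}

#' @export
print.summary.it_model <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Accepted thresholds of a fitted model
#'
#' @param object an `"it_model"`; @param ... unused.
#' @return Named numeric vector of thresholds (`NA` = rejected output).
#' @export
coef.it_model <- function(object, ...) {
  stats::setNames(object$thresholds, object$labels)
}

#' Predict Intervention-Time alarms on a new record
#'
#' Runs the feature pipeline on the test record with the model's
#' configuration and applies the vote-based SOP thresholding
#' ([predict_alarms()]).
#'
#' @param object an `"it_model"`.
#' @param record an [eeg_record()] (or an `"envelope_bank"` already computed
#'   via [pipeline_features()]).
#' @param ... unused.
#' @return An `"it_prediction"`.
#' @export
predict.it_model <- function(object, record, ...) {
  bank <- if (inherits(record, "envelope_bank")) record
          else pipeline_features(record, object$config)
  predict_alarms(bank, object)
}

#' Plot a model output envelope with its threshold
#'
#' Shows one training record's envelope for a chosen output, the accepted
#' threshold (if any), and the annotated IT / ictal onsets.
#'
#' @param x an `"it_model"`.
#' @param output output index 1..12.
#' @param record_index which training record to show.
#' @param ... passed to [plot()].
#' @export
plot.it_model <- function(x, output = 1L, record_index = 1L, ...) {
  bank <- x$train_envelopes[[record_index]]
  env <- bank$series[[output]]
  t <- fs_times(env)
  plot(t, env$values, type = "l", xlab = "time (s)",
       ylab = sprintf("envelope, output %s", x$labels[output]), ...)
  if (x$accepted[output])
    abline(h = x$thresholds[output], lty = 2)
  it_on <- annotation_time_df(bank$annotations, "it_onset")
  ict_on <- annotation_time_df(bank$annotations, "ictal_onset")
  if (!is.na(it_on)) abline(v = it_on, col = "darkorange")
  if (!is.na(ict_on)) abline(v = ict_on, col = "firebrick")
  invisible(x)
}

#' Evaluate a prediction against a record's annotations
#'
#' Confusion counts over SOP windows plus the performance criteria. The
#' interictal hours for the FPR default to the record span before IT onset
#' (the whole record when no seizure is annotated).
#'
#' @param prediction an `"it_prediction"`.
#' @param truth annotations `data.frame` (`label`, `time_s`); defaults to
#'   the annotations carried by the prediction.
#' @param interictal_hours override for the FPR denominator.
#' @return An [eval_metrics()] report with the per-seizure
#'   [prediction_time()] table attached as `prediction_times`.
#' @export
it_evaluate <- function(prediction, truth = NULL, interictal_hours = NULL) {
  stopifnot(inherits(prediction, "it_prediction"))
  truth <- truth %||% prediction$annotations
  cf <- confusion(prediction, truth)
  if (is.null(interictal_hours)) {
    it_on <- annotation_time_df(truth, "it_onset")
    span <- max(prediction$windows$end) - min(prediction$windows$start)
    interictal_hours <- (if (is.na(it_on)) span else
                         it_on - min(prediction$windows$start)) / 3600
  }
  rep <- eval_metrics(cf$tp, cf$tn, cf$fp, cf$fn, interictal_hours)
  rep$prediction_times <- prediction_time(prediction, truth)
  rep
}
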