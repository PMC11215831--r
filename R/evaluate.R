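#' SOP-window confusion counts
#'
#' Each SOP window is positive when it overlaps the true IT-to-ictal-onset
#' interval, negative otherwise; flagged windows then split into TP/FP and
#' unflagged into FN/TN.
#'
#' @param prediction an [predict_alarms()] result.
#' @param truth `data.frame` of annotations (`label`, `time_s`) with
#'   `it_onset` and `ictal_onset`.
#' @return Named list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(prediction, truth) {
  stopifnot(inherits(prediction, "it_prediction"))
  if (is.null(truth)) stop_bad("missing annotations")
  it_on <- annotation_time_df(truth, "it_onset")
  ict_on <- annotation_time_df(truth, "ictal_onset")
  w <- prediction$windows
  positive <- if (is.na(it_on)) rep(FALSE, nrow(w)) else {
    pos_end <- if (is.na(ict_on)) it_on + prediction$sop_s else ict_on
    w$start < pos_end & w$end > it_on
  }
  list(tp = sum(w$flagged & positive), tn = sum(!w$flagged & !positive),
       fp = sum(w$flagged & !positive), fn = sum(!w$flagged & positive))
}

#' Prediction performance criteria
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`, each expressed in percent, plus the false
#' prediction rate `FP / interictal hours`. Ratios with zero denominator are
#' reported as `NA` (undefined), never as 0.
#'
#' @param tp,tn,fp,fn confusion counts (non-negative).
#' @param interictal_hours hours of interictal data, for the FPR.
#' @return An object of class `"eval_report"` with the counts and metrics.
#' @export
eval_metrics <- function(tp, tn, fp, fn, interictal_hours = NA_real_) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop_bad("negative confusion counts")
  rat <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = rat(tp + tn, tp + tn + fp + fn),
                 sensitivity = rat(tp, tp + fn),
                 specificity = rat(tn, tn + fp),
                 fpr = if (!is.na(interictal_hours) && interictal_hours > 0)
                         fp / interictal_hours else NA_real_,
                 interictal_hours = interictal_hours),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TP %d TN %d FP %d FN %d | sens %s%% spec %s%% acc %s%% FPR %s/h\n",
              x$tp, x$tn, x$fp, x$fn,
              fmt1(x$sensitivity), fmt1(x$specificity), fmt1(x$accuracy),
              fmt1(x$fpr)))
  invisible(x)
}

fmt1 <- function(v) if (is.na(v)) "--" else sprintf("%.1f", v)

#' Aggregate evaluation reports across patients
#'
#' Arithmetic mean of each metric over the patients for whom it is defined:
#' patients without ictal test data contribute only specificity and FPR,
#' while sensitivity and accuracy are averaged over the remaining patients.
#'
#' @param reports list of [eval_metrics()] reports (or lists with the same
#'   metric fields; `NA` marks an undefined metric).
#' @return Named list of mean `sensitivity`, `specificity`, `accuracy`,
#'   `fpr`, plus `n` per metric.
#' @export
aggregate_reports <- function(reports) {
  if (!length(reports)) stop_bad("no reports to aggregate")
  one <- function(field) {
    v <- vapply(reports, function(r) as.numeric(r[[field]] %||% NA_real_),
                numeric(1))
    list(mean = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
         n = sum(!is.na(v)))
  }
  m <- lapply(c(sensitivity = "sensitivity", specificity = "specificity",
                accuracy = "accuracy", fpr = "fpr"), one)
  list(sensitivity = m$sensitivity$mean, specificity = m$specificity$mean,
       accuracy = m$accuracy$mean, fpr = m$fpr$mean,
       n = vapply(m, function(e) e$n, numeric(1)))
}

#' Per-seizure prediction times
#'
#' For each true seizure whose SOP window received an alarm, reports both
#' readings of "prediction time": `time_to_ictal = ictal_onset - alarm_time`
#' (margin before the seizure) and `latency_from_it = alarm_time - it_onset`
#' (delay after the IT state began). Missed seizures yield no entry.
#'
#' @param prediction an [predict_alarms()] result.
#' @param truth annotations `data.frame` with `it_onset` / `ictal_onset`.
#' @return `data.frame` with columns `alarm_time`, `time_to_ictal`,
#'   `latency_from_it` (zero rows when no seizure was predicted).
#' @export
prediction_time <- function(prediction, truth) {
  stopifnot(inherits(prediction, "it_prediction"))
  it_on <- annotation_time_df(truth, "it_onset")
  ict_on <- annotation_time_df(truth, "ictal_onset")
  out <- data.frame(alarm_time = numeric(0), time_to_ictal = numeric(0),
                    latency_from_it = numeric(0))
  if (is.na(it_on)) return(out)
  pos_end <- if (is.na(ict_on)) it_on + prediction$sop_s else ict_on
  w <- prediction$windows
  hit <- w$flagged & w$start < pos_end & w$end > it_on & !is.na(w$alarm_time)
  if (!any(hit)) return(out)
  alarm <- min(w$alarm_time[hit])
  data.frame(alarm_time = alarm,
             time_to_ictal = if (is.na(ict_on)) NA_real_ else ict_on - alarm,
             latency_from_it = alarm - it_on)
}
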