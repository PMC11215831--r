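#' Two-channel EEG record container
#'
#' Holds the two analysis channels (main/focal and contralateral), the
#' sampling rate, per-record seizure annotations, and a patient identifier.
#' Channel selection is deliberately manual: the pipeline assumes the first
#' channel is the seizure focus and the second the channel opposite it.
#'
#' @param data numeric matrix, one column per channel (equal lengths).
#' @param fs sampling rate (Hz).
#' @param channel_labels character vector of column labels.
#' @param annotations `data.frame` with columns `label`
#'   (`it_onset` / `ictal_onset` / `ictal_offset`) and `time_s`; times must
#'   fall inside the record.
#' @param patient_id identifier string.
#' @return An object of class `"eeg_record"`.
#' @export
eeg_record <- function(data, fs, channel_labels = colnames(data),
                       annotations = NULL, patient_id = "unknown") {
  data <- as.matrix(data)
  check_scalar(fs, "fs", 0, strict_lower = TRUE)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncol(data)))
  if (length(channel_labels) != ncol(data))
    stop_bad("one label per channel required")
  colnames(data) <- channel_labels
  dur <- nrow(data) / fs
  if (is.null(annotations))
    annotations <- data.frame(label = character(0), time_s = numeric(0),
                              stringsAsFactors = FALSE)
  stopifnot(is.data.frame(annotations),
            all(c("label", "time_s") %in% names(annotations)))
  if (nrow(annotations) && any(annotations$time_s < 0 | annotations$time_s > dur))
    stop_bad("annotation times outside record duration")
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 annotations = annotations, patient_id = patient_id),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> patient %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (nrow(x$annotations))
    cat("  annotations:", paste(sprintf("%s@%gs", x$annotations$label,
                                        x$annotations$time_s), collapse = ", "), "\n")
  invisible(x)
}

record_duration <- function(record) nrow(record$data) / record$fs

annotation_time <- function(record, label) {
  t <- record$annotations$time_s[record$annotations$label == label]
  if (length(t)) t[1] else NA_real_
}

sidecar_paths <- function(path) {
  base <- sub("\\.csv$", "", path)
  list(meta = paste0(base, ".meta.json"), annot = paste0(base, ".annot.csv"))
}

#' Write an EEG record to delimited text
#'
#' Writes the samples as CSV with header `time_s,ch_main,ch_contra` ("." as
#' decimal separator), plus two sidecars: `<base>.meta.json` (sampling rate,
#' labels, patient id) and `<base>.annot.csv` (`label,time_s`), written only
#' when annotations exist. Round-trips losslessly to the printed precision
#' (15 significant digits).
#'
#' @param record an [eeg_record()].
#' @param path output path ending in `.csv`.
#' @return `path`, invisibly.
#' @export
write_eeg_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  if (!all(is.finite(record$data)))
    stop_bad("record contains non-finite samples")
  n <- nrow(record$data)
  df <- data.frame(time_s = (seq_len(n) - 1L) / record$fs)
  for (j in seq_len(ncol(record$data)))
    df[[record$channel_labels[j]]] <- record$data[, j]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  sp <- sidecar_paths(path)
  jsonlite::write_json(list(fs = record$fs,
                            channel_labels = record$channel_labels,
                            patient_id = record$patient_id),
                       sp$meta, auto_unbox = TRUE, digits = NA)
  if (nrow(record$annotations))
    utils::write.csv(record$annotations, sp$annot, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EEG record from delimited text
#'
#' Reads the CSV dialect written by [write_eeg_record()] and restricts the
#' record to the two requested channels in (main, contralateral) order.
#' The sampling rate is taken from the `.meta.json` sidecar when present,
#' otherwise inferred from the `time_s` column; annotations are read from the
#' `.annot.csv` sidecar when present.
#'
#' @param path CSV file path.
#' @param main_channel,contra_channel channel labels to select; default: the
#'   first two data columns in file order.
#' @return An [eeg_record()] with exactly two channels.
#' @export
read_eeg_record <- function(path, main_channel = NULL, contra_channel = NULL) {
  if (!file.exists(path)) stop_bad("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df) || ncol(df) < 2L)
    stop_bad("not a recognized EEG CSV (need `time_s` plus channel columns): ", path)
  chans <- setdiff(names(df), "time_s")
  sp <- sidecar_paths(path)
  meta <- if (file.exists(sp$meta)) jsonlite::read_json(sp$meta, simplifyVector = TRUE) else NULL
  fs <- meta$fs %||% (1 / stats::median(diff(df$time_s)))
  main_channel <- main_channel %||% chans[1]
  contra_channel <- contra_channel %||% chans[2]
  for (ch in c(main_channel, contra_channel))
    if (is.na(ch) || !ch %in% chans)
      stop_bad(sprintf("channel not found: \"%s\" (available: %s)",
                       ch, paste(chans, collapse = ", ")))
  ann <- if (file.exists(sp$annot)) utils::read.csv(sp$annot) else NULL
  eeg_record(as.matrix(df[, c(main_channel, contra_channel)]), fs = fs,
             channel_labels = c(main_channel, contra_channel),
             annotations = ann,
             patient_id = meta$patient_id %||% "unknown")
}
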