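# shared fixtures, all generated in code

# stable, strongly resonant AR(8): four conjugate pole pairs; coefficients
# from expanding prod_i (1 - 2 r cos(th_i) z^-1 + r^2 z^-2)
ar8_true <- function(r = 0.95, freqs = c(0.06, 0.12, 0.20, 0.30)) {
  a <- 1
  for (th in 2 * pi * freqs) {
    q <- c(1, -2 * r * cos(th), r^2)
    a <- convolve(a, rev(q), type = "open")
  }
  -a[-1]  # phi such that x_k = sum phi_j x_{k-j} + e_k
}

simulate_ar <- function(phi, n, sd = 1, burn = 500L) {
  e <- rnorm(n + burn, sd = sd)
  x <- as.numeric(stats::filter(e, phi, method = "recursive"))
  x[(burn + 1L):(burn + n)]
}

# short synthetic two-channel record for fast end-to-end tests
quick_record <- function(seed, t_it = 200, t_ictal = 230, t_end = 300) {
  generate_record(seizure_model_params(seed = seed),
                  default_schedule(t_it, t_ictal, t_end))
}

# hand-built envelope bank (list shape consumed by train_thresholds /
# predict_alarms) from a matrix of envelope values, one column per output
make_env_bank <- function(values, rate = 1, t0 = 0, annotations = NULL,
                          patient_id = "fixture") {
  series <- lapply(seq_len(ncol(values)), function(j)
    feature_series(values[, j], rate = rate, t0 = t0))
  list(series = series, labels = paste0("out", seq_len(ncol(values))),
       annotations = annotations, patient_id = patient_id)
}

ann_df <- function(it_onset = NA, ictal_onset = NA, ictal_offset = NA) {
  lab <- c("it_onset", "ictal_onset", "ictal_offset")
  t <- c(it_onset, ictal_onset, ictal_offset)
  data.frame(label = lab[!is.na(t)], time_s = t[!is.na(t)],
             stringsAsFactors = FALSE)
}

# minimal trained-model stand-in for voting tests
make_model <- function(thresholds, sop_s = 100) {
  accepted <- !is.na(thresholds)
  structure(list(thresholds = thresholds, accepted = accepted,
                 K = sum(accepted), quorum = as.integer(ceiling(sum(accepted) / 2)),
                 sop_s = sop_s, sustain_s = 0,
                 labels = paste0("out", seq_along(thresholds)),
                 patient_id = "fixture"),
            class = "it_model")
}
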