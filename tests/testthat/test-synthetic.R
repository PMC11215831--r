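test_that("model parameter validation enforces stability and ordering", {
  expect_error(seizure_model_params(h1_coeffs = c(1, -2, 1.2)), "unstable")
  expect_error(seizure_model_params(f_m_it = 2, f_m_ictal = 1.5), "strictly below")
  expect_error(seizure_model_params(f_m_ictal = 20), "out of range")
  expect_error(seizure_model_params(amp_ictal = 1, amp_it = 2), "strictly below")
  p <- seizure_model_params()
  expect_equal(p$amp_ictal / p$bg_rms, 3)
  expect_equal(p$amp_it / p$bg_rms, 1.5)
})

test_that("background generator is seeded, zero under zero noise, stationary", {
  p0 <- seizure_model_params(noise_sigma = 0, amp_ictal = 2, amp_it = 1)
  expect_equal(generate_background(p0, 1000), rep(0, 1000))

  p <- seizure_model_params()
  set.seed(7); a <- generate_background(p, 4096)
  set.seed(7); b <- generate_background(p, 4096)
  expect_identical(a, b)
  expect_lt(abs(mean(a)), 3 * sd(a) / sqrt(100))  # near zero mean

  set.seed(1)
  x <- generate_background(p, 60 * 256)
  h1 <- var(x[1:(length(x) / 2)]); h2 <- var(x[(length(x) / 2 + 1):length(x)])
  expect_lt(max(h1, h2) / min(h1, h2), 3)
})

test_that("background spectrum matches the analytic all-pole response", {
  p <- seizure_model_params(seed = 42)
  set.seed(42)
  n <- 65536
  x <- generate_background(p, n)
  # averaged periodogram over 16 chunks vs sigma^2 |1/H1|^2 / fs, compared as
  # band-integrated power in three bands
  nb <- 4096
  pxx <- rowMeans(sapply(seq_len(16), function(i) {
    seg <- x[((i - 1) * nb + 1):(i * nb)]
    Mod(fft(seg))^2 / nb
  }))
  f <- (0:(nb - 1)) / nb * p$fs
  H <- function(f) {
    z <- exp(-2i * pi * f / p$fs)
    Mod(1 / (1 + p$h1_coeffs[2] * z + p$h1_coeffs[3] * z^2))^2 * p$noise_sigma^2
  }
  for (band in list(c(1, 8), c(8, 20), c(20, 60))) {
    sel <- f >= band[1] & f < band[2]
    expect_equal(mean(pxx[sel]), mean(H(f[sel])), tolerance = 0.1)
  }
})

test_that("seizure component peaks at f_m and respects amplitude ordering", {
  p <- seizure_model_params()
  expect_equal(generate_seizure_component(p, 1000, 1.5, 0), rep(0, 1000))
  expect_error(generate_seizure_component(p, 1000, 200, 1), "alias")

  n <- 51200
  s <- generate_seizure_component(p, n, 1.5, p$amp_ictal)
  spec <- Mod(fft(s))[2:(n / 2)]
  f <- (1:(n / 2 - 1)) * p$fs / n
  expect_lt(abs(f[which.max(spec)] - 1.5), p$fs / n + 1e-9)

  s_it <- generate_seizure_component(p, n, p$f_m_it, p$amp_it)
  expect_lt(sqrt(mean(s_it^2)), sqrt(mean(s^2)))
  expect_equal(sqrt(mean(s^2)), p$amp_ictal, tolerance = 1e-9)
})

test_that("generated records order variance by state and carry ground truth", {
  p <- seizure_model_params(seed = 5)
  sch <- default_schedule(t_it = 100, t_ictal = 130, t_end = 200)
  rec <- generate_record(p, sch)
  fs <- rec$fs
  v_int <- var(rec$data[1:(95 * fs), 1])
  v_it <- var(rec$data[(101 * fs):(129 * fs), 1])
  v_ict <- var(rec$data[(131 * fs):(199 * fs), 1])
  expect_gt(v_ict, v_it)
  expect_gt(v_it, v_int)
  expect_equal(rec$annotations$time_s[rec$annotations$label == "it_onset"], 100)
  expect_equal(rec$annotations$time_s[rec$annotations$label == "ictal_onset"], 130)

  # seeded generation is bit-reproducible
  expect_identical(generate_record(p, sch)$data,
                   generate_record(seizure_model_params(seed = 5), sch)$data)
})

test_that("all-interictal schedules give pure background on both channels", {
  sch <- state_schedule("interictal", 0, 60)
  p <- seizure_model_params(seed = 3)
  rec <- generate_record(p, sch)
  set.seed(3)
  expect_equal(rec$data[, 1], generate_background(p, nrow(rec$data)))
})

test_that("zero contralateral gain removes the seizure component from channel 2", {
  p <- seizure_model_params(seed = 9, contralateral_gain = 0)
  rec <- generate_record(p, default_schedule(t_it = 10, t_ictal = 40, t_end = 120))
  fs <- rec$fs
  seg <- rec$data[(41 * fs):(119 * fs), 2]
  n <- length(seg)
  f <- (1:(n %/% 2)) * fs / n
  spec <- Mod(fft(seg))[2:(n %/% 2 + 1)]
  # no line at the ictal fundamental: the 1.5 Hz bin is not the argmax
  sel <- f > 0.5 & f < 3
  expect_gt(abs(f[sel][which.max(spec[sel])] - 1.5), 2 * fs / n)
})

test_that("schedule validation rejects malformed state sequences", {
  expect_error(state_schedule(character(0), numeric(0), numeric(0)), "empty|arg")
  expect_error(state_schedule(c("interictal", "ictal"), c(0, 100), c(100, 200)),
               "preceded")
  expect_error(state_schedule(c("interictal", "it"), c(0, 150), c(100, 200)),
               "contiguous")
  expect_error(state_schedule("interictal", 10, 100), "start at t = 0")
})

test_that("shaping-filter fits recover known AR(2) dynamics", {
  set.seed(11)
  # white-noise limit: no coloring
  w <- rnorm(20000)
  fw <- fit_shaping_filters(w, 2)
  expect_equal(length(fw$h1_coeffs), 3L)
  expect_equal(fw$h1_coeffs[1], 1)
  expect_lt(max(abs(fw$h1_coeffs[2:3])), 0.05)

  # parameter recovery on a known stable AR(2)
  a_true <- c(1, -1.5, 0.7)
  set.seed(12)
  x <- simulate_ar(-a_true[-1], 100000)
  fx <- fit_shaping_filters(x, 2)
  expect_equal(fx$h1_coeffs, a_true, tolerance = 0.05)
  expect_true(all(Mod(polyroot(rev(fx$h1_coeffs))) < 1))

  expect_error(fit_shaping_filters(rep(1, 100), 2), "degenerate")
})
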