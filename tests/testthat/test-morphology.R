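# naive sliding-sort oracle for the causal median of squares
fg_oracle <- function(x, q) {
  vapply(seq_along(x), function(k) {
    w <- x[max(1, k - q + 1):k]^2
    median(sort(w))
  }, numeric(1))
}

mcfg <- function(...) morph_config(warmup_s = 0, ...)

test_that("foreground matches the naive sliding-sort median oracle", {
  set.seed(51)
  x <- feature_series(rnorm(300), rate = 2)
  cfg <- mcfg()                      # 1 s at 2 Hz -> min_window 3
  expect_equal(foreground(x, cfg)$values, fg_oracle(x$values, 3))

  xl <- feature_series(rnorm(500), rate = 11)
  expect_equal(foreground(xl, cfg)$values, fg_oracle(xl$values, 11))
})

test_that("foreground fixed points and outlier robustness", {
  cfg <- mcfg()
  const <- feature_series(rep(3, 50), rate = 2)
  expect_equal(foreground(const, cfg)$values, rep(9, 50))

  alt <- feature_series(rep(c(1, -1), 25), rate = 2)
  expect_equal(foreground(alt, cfg)$values, rep(1, 50))

  # a single extreme outlier inside an 11-sample window leaves the median
  # at the sorted-window middle
  set.seed(52)
  v <- rnorm(100); v[60] <- 1e6
  x <- feature_series(v, rate = 11)
  fg <- foreground(x, cfg)
  expect_equal(fg$values, fg_oracle(v, 11))
  expect_lt(fg$values[65], 100)      # not dragged up by the outlier
  expect_error(foreground(feature_series(numeric(0), 1), cfg))
})

test_that("background follows the exponential-forgetting recursion exactly", {
  cfg <- mcfg()                       # q2 = 3, s = 1 at 2 Hz
  # constant foreground is a fixed point
  fg <- feature_series(rep(4, 60), rate = 2)
  bg <- background(fg, cfg)
  expect_true(all(is.na(bg$values[1:2])))
  expect_equal(bg$values[-(1:2)], rep(4, 58))

  # step c -> 2c approaches 2c geometrically with ratio lambda per update
  lam <- cfg$lambda_bg
  k0 <- 40
  v <- c(rep(2, k0), rep(4, 60))
  bg2 <- background(feature_series(v, rate = 2), cfg)$values
  # from the first update whose median window sits wholly in the new regime
  start <- k0 + 3L
  b_start <- bg2[start - 1L]
  m <- seq_len(50)
  closed <- 4 - (4 - b_start) * lam^m
  expect_equal(bg2[start - 1L + m], closed, tolerance = 1e-9)
})

test_that("background limits: no memory as lambda -> 0", {
  cfg <- mcfg(lambda_bg = 1e-9)
  set.seed(53)
  v <- abs(rnorm(40))
  bg <- background(feature_series(v, rate = 2), cfg)$values
  med3 <- vapply(3:40, function(k) median(v[(k - 2):k]), numeric(1))
  expect_equal(bg[3:40], med3, tolerance = 1e-6)
})

test_that("background scales jointly with the foreground", {
  set.seed(54)
  cfg <- mcfg()
  fgv <- abs(rnorm(80))
  b1 <- background(feature_series(fgv, 2), cfg)$values
  b2 <- background(feature_series(5 * fgv, 2), cfg)$values
  expect_equal(b2, 5 * b1, tolerance = 1e-12)
})

test_that("ratio bank structure, stationarity fixed point and step response", {
  set.seed(55)
  n <- 400
  # stationary series at the pipeline's operating point (first-cepstrum
  # values: positive mean, modest spread); heavy-skew inputs bias the
  # median-based FG/BG pair apart and the self-ratio off 1
  mk <- function() feature_series(rnorm(n, mean = 2.5, sd = 0.3), rate = 2)
  cb <- structure(list(series = c(replicate(6, mk(), simplify = FALSE),
                                  replicate(6, mk(), simplify = FALSE)),
                       labels = paste0("s", 1:12),
                       annotations = NULL, patient_id = "p"),
                  class = "ceps_bank")
  rb <- ratio_bank(cb, mcfg())
  expect_length(rb$series, 12)
  expect_equal(rb$labels[c(1, 7)], c("r1_D1", "r2_D1"))
  # stationary input: time-average of the self-ratio near 1 after warm-up
  r1 <- rb$series[[1]]$values
  expect_equal(mean(r1[100:n], na.rm = TRUE), 1, tolerance = 0.05)
  expect_true(all(rb$series[[1]]$values >= 0, na.rm = TRUE))

  # abrupt main-channel energy doubling lifts r2 toward 2 before BG adapts
  cbs <- cb
  stepv <- c(rep(1, 200), rep(sqrt(2), 200)) * cbs$series[[1]]$values
  cbs$series[[1]] <- feature_series(stepv, rate = 2)
  rbs <- ratio_bank(cbs, mcfg())
  r2 <- rbs$series[[7]]$values
  after <- mean(r2[206:220], na.rm = TRUE)
  before <- mean(r2[150:200], na.rm = TRUE)
  expect_gt(after / before, 1.5)
})

test_that("warm-up masking blanks the leading seconds of the ratios", {
  set.seed(56)
  mk <- function() feature_series(rnorm(100), rate = 2)
  cb <- structure(list(series = c(replicate(6, mk(), simplify = FALSE),
                                  replicate(6, mk(), simplify = FALSE)),
                       labels = paste0("s", 1:12), annotations = NULL,
                       patient_id = "p"),
                  class = "ceps_bank")
  rb <- ratio_bank(cb, morph_config(warmup_s = 10))
  r <- rb$series[[4]]
  expect_true(all(is.na(r$values[fs_times(r) < 10])))
  expect_false(anyNA(r$values[fs_times(r) >= 10]))
})
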