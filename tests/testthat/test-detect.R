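test_that("moving average matches a brute-force window-mean oracle", {
  cfg <- envelope_config()                # 2 s window, 1 s overlap
  s <- feature_series(as.numeric(0:99), rate = 2)   # w = 4, hop = 2
  av <- moving_average(s, cfg)
  oracle <- vapply(seq(1, 97, by = 2), function(i) mean((i - 1):(i + 2)),
                   numeric(1))
  expect_equal(av$values, oracle)
  expect_equal(av$rate, 1)

  const <- feature_series(rep(7, 20), rate = 2)
  expect_equal(moving_average(const, cfg)$values, rep(7, 9))

  # NaN-containing windows are excluded
  v <- rep(1, 20); v[6] <- NA
  avn <- moving_average(feature_series(v, rate = 2), cfg)$values
  expect_true(is.na(avn[2]) && is.na(avn[3]))
  expect_false(anyNA(avn[-c(2, 3)]))

  expect_error(moving_average(feature_series(1:2, rate = 2), cfg), "shorter")
})

test_that("positive envelope tracks a slow amplitude modulator", {
  fs <- 50
  t <- seq(0, 60, by = 1 / fs)
  A <- 2 + sin(2 * pi * t / 30)
  x <- feature_series(A * sin(2 * pi * 2 * t), rate = fs)
  env <- positive_envelope(x, envelope_config(peak_min_separation = 10))
  core <- t > 5 & t < 55
  expect_lt(max(abs(env$values[core] - A[core]) / A[core]), 0.05)
})

test_that("degenerate envelope inputs fall back sensibly", {
  cfg <- envelope_config()
  const <- feature_series(rep(2.5, 40), rate = 1)
  expect_warning(env <- positive_envelope(const, cfg), "fewer than 2 peaks")
  expect_equal(env$values, rep(2.5, 40))

  mono <- feature_series(as.numeric(1:50), rate = 1)
  expect_warning(envm <- positive_envelope(mono, cfg))
  expect_true(all(envm$values >= 1 & envm$values <= 50))

  # leading NA warm-up is preserved
  v <- c(rep(NA, 5), sin(seq(0, 20, by = 0.2)) + 2)
  env2 <- positive_envelope(feature_series(v, rate = 1),
                            envelope_config(peak_min_separation = 3))
  expect_true(all(is.na(env2$values[1:5])))
  expect_false(anyNA(env2$values[-(1:5)]))
})

test_that("threshold training separates separable outputs and rejects others", {
  # output 1: interictal ~1.0, ramps to 2.0 in IT; output 2: flat (inseparable)
  n <- 400                                    # 400 s at 1 Hz
  set.seed(61)
  base <- 1 + 0.02 * rnorm(n)
  ramp <- base; ramp[361:390] <- seq(1, 2, length.out = 30)
  flat <- 1 + 0.02 * rnorm(n)
  bank <- make_env_bank(cbind(ramp, flat), rate = 1,
                        annotations = ann_df(it_onset = 360, ictal_onset = 390))
  model <- train_thresholds(list(bank))
  expect_true(model$accepted[1])
  expect_false(model$accepted[2])
  expect_gt(model$thresholds[1], 1.0)
  expect_lte(model$thresholds[1], 2.0)
  expect_equal(model$K, 1L)
  expect_equal(model$quorum, 1L)

  # nothing separable -> training failure
  bank2 <- make_env_bank(cbind(flat, flat), rate = 1,
                         annotations = ann_df(it_onset = 360, ictal_onset = 390))
  expect_error(train_thresholds(list(bank2)), "training failure")

  # no IT annotation anywhere -> error
  bank3 <- make_env_bank(cbind(ramp, flat), rate = 1, annotations = ann_df())
  expect_error(train_thresholds(list(bank3)), "IT onset")
})

test_that("trained thresholds produce zero interictal crossings on training data", {
  set.seed(62)
  n <- 500
  vals <- sapply(1:4, function(j) {
    v <- 1 + 0.05 * abs(rnorm(n))
    v[451:480] <- v[451:480] + j / 2   # IT bumps of varying size
    v
  })
  bank <- make_env_bank(vals, rate = 1,
                        annotations = ann_df(it_onset = 450, ictal_onset = 480))
  model <- train_thresholds(list(bank))
  for (j in which(model$accepted)) {
    inter <- vals[1:450, j]
    expect_true(all(inter <= model$thresholds[j]))
  }
})

test_that("SOP voting follows the ceil(K/2) quorum rule", {
  # 7 accepted outputs (thresholds 1), one 100-s window, controllable firing
  n <- 100
  fire <- function(k) {
    m <- matrix(0.5, n, 7)
    for (j in seq_len(k)) m[50 + j, j] <- 1.5   # j-th output crosses once
    m
  }
  model <- make_model(rep(1, 7))
  expect_equal(model$quorum, 4L)
  bank4 <- make_env_bank(fire(4), rate = 1, annotations = ann_df())
  p4 <- predict_alarms(bank4, model)
  expect_true(any(p4$windows$flagged))
  expect_equal(p4$windows$votes[1], 4L)
  # alarm at the quorum-th (4th) crossing instant: sample 54 is at t = 53
  expect_equal(p4$windows$alarm_time[1], 53)

  bank3 <- make_env_bank(fire(3), rate = 1, annotations = ann_df())
  p3 <- predict_alarms(bank3, model)
  expect_false(any(p3$windows$flagged))

  bank0 <- make_env_bank(matrix(0.5, n, 7), rate = 1, annotations = ann_df())
  expect_length(predict_alarms(bank0, model)$alarm_times, 0)

  # all-rejected model refuses to predict
  expect_error(predict_alarms(bank4, make_model(rep(NA_real_, 7))),
               "no accepted outputs")
  expect_error(predict_alarms(make_env_bank(matrix(1, n, 3)), model),
               "mismatch")
})

test_that("raising a threshold never increases the number of flagged windows", {
  set.seed(63)
  for (trial in 1:10) {
    vals <- matrix(runif(300 * 5, 0, 2), 300, 5)
    bank <- make_env_bank(vals, rate = 1, annotations = ann_df())
    thr <- runif(5, 0.5, 1.5)
    m1 <- make_model(thr)
    j <- sample(5, 1)
    thr2 <- thr; thr2[j] <- thr2[j] + runif(1, 0, 0.5)
    m2 <- make_model(thr2)
    expect_lte(sum(predict_alarms(bank, m2)$windows$flagged),
               sum(predict_alarms(bank, m1)$windows$flagged))
  }
})

test_that("the SOP grid is anchored at the ictal onset when annotated", {
  set.seed(64)
  vals <- matrix(runif(400 * 2), 400, 2)
  bank <- make_env_bank(vals, rate = 1,
                        annotations = ann_df(it_onset = 310, ictal_onset = 330))
  p <- predict_alarms(bank, make_model(c(2, 2)))
  expect_true(any(abs(p$windows$start - 330) < 1e-9) ||
              any(abs(p$windows$end - 330) < 1e-9))
  # determinism
  p2 <- predict_alarms(bank, make_model(c(2, 2)))
  expect_identical(p$windows, p2$windows)
})
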