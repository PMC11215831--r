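# build an it_prediction by hand from window flags
make_pred <- function(starts, sop_s, flagged, alarm_times = NULL) {
  w <- data.frame(start = starts, end = starts + sop_s,
                  votes = as.integer(flagged), flagged = flagged,
                  alarm_time = alarm_times %||% ifelse(flagged, starts + 1, NA))
  structure(list(windows = w, alarm_times = w$alarm_time[w$flagged],
                 crossing_times = list(), sop_s = sop_s,
                 annotations = NULL, patient_id = "fixture"),
            class = "it_prediction")
}

test_that("confusion counts match window-by-window enumeration", {
  # 10 clean windows, nothing flagged
  p <- make_pred(seq(0, 900, by = 100), 100, rep(FALSE, 10))
  cf <- confusion(p, ann_df(it_onset = NA, ictal_onset = NA))
  expect_equal(cf, list(tp = 0L, tn = 10L, fp = 0L, fn = 0L))
  expect_error(confusion(p, NULL), "missing annotations")

  # 1 seizure correctly flagged, 9 clean windows unflagged
  fl <- c(rep(FALSE, 9), TRUE)
  p2 <- make_pred(seq(0, 900, by = 100), 100, fl)
  cf2 <- confusion(p2, ann_df(it_onset = 910, ictal_onset = 940))
  expect_equal(cf2, list(tp = 1L, tn = 9L, fp = 0L, fn = 0L))

  # randomized layouts vs an exhaustive oracle
  set.seed(71)
  for (trial in 1:20) {
    nw <- sample(4:12, 1)
    starts <- seq(0, by = 100, length.out = nw)
    flagged <- runif(nw) < 0.4
    it_on <- runif(1, 0, nw * 100 - 50)
    ict_on <- it_on + runif(1, 10, 80)
    p <- make_pred(starts, 100, flagged)
    cf <- confusion(p, ann_df(it_onset = it_on, ictal_onset = ict_on))
    pos <- starts < ict_on & (starts + 100) > it_on
    expect_equal(cf$tp, sum(flagged & pos))
    expect_equal(cf$fp, sum(flagged & !pos))
    expect_equal(cf$fn, sum(!flagged & pos))
    expect_equal(cf$tn, sum(!flagged & !pos))
  }
})

test_that("performance criteria follow the standard confusion formulas", {
  r <- eval_metrics(1, 9, 0, 0, interictal_hours = 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$accuracy, 100)
  expect_equal(r$fpr, 0)

  r2 <- eval_metrics(3, 5, 1, 1, interictal_hours = 2)
  expect_equal(r2$accuracy, 80)
  expect_equal(r2$sensitivity, 75)
  expect_equal(r2$specificity, 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(r2$fpr, 0.5)

  r0 <- eval_metrics(0, 0, 0, 0)
  expect_true(is.na(r0$accuracy) && is.na(r0$sensitivity) &&
              is.na(r0$specificity) && is.na(r0$fpr))
  expect_error(eval_metrics(-1, 0, 0, 0), "negative")
})

test_that("the accuracy identity holds over random counts", {
  set.seed(72)
  for (trial in 1:50) {
    k <- sample(0:30, 4, replace = TRUE)
    if (sum(k) == 0) next
    r <- eval_metrics(k[1], k[2], k[3], k[4])
    expect_equal(r$accuracy * sum(k), 100 * (k[1] + k[2]), tolerance = 1e-12)
  }
})

test_that("aggregation averages only the patients with defined metrics", {
  reports <- list(
    list(sensitivity = 75, specificity = 88.3, accuracy = 86.9, fpr = 4.19),
    list(sensitivity = 100, specificity = 98.4, accuracy = 98.5, fpr = 0.5),
    list(sensitivity = NA, specificity = 100, accuracy = NA, fpr = 0)
  )
  agg <- aggregate_reports(reports)
  expect_equal(agg$sensitivity, 87.5)
  expect_equal(agg$specificity, mean(c(88.3, 98.4, 100)))
  expect_equal(agg$accuracy, mean(c(86.9, 98.5)))
  expect_equal(unname(agg$n["sensitivity"]), 2)

  expect_equal(aggregate_reports(reports[1])$accuracy, 86.9)
  expect_error(aggregate_reports(list()), "no reports")
  # permutation invariance
  agg_p <- aggregate_reports(rev(reports))
  expect_equal(agg_p$specificity, agg$specificity)
})

test_that("prediction times report both readings", {
  p <- make_pred(c(270, 370), 100, c(TRUE, FALSE), alarm_times = c(370, NA))
  pt <- prediction_time(p, ann_df(it_onset = 360, ictal_onset = 370))
  expect_equal(pt$latency_from_it, 10)
  expect_equal(pt$time_to_ictal, 0)

  p2 <- make_pred(c(930), 100, TRUE, alarm_times = 1010)
  pt2 <- prediction_time(p2, ann_df(it_onset = 1000, ictal_onset = 1030))
  expect_equal(pt2$time_to_ictal, 20)
  expect_equal(pt2$latency_from_it, 10)

  # missed seizures yield no entry
  p3 <- make_pred(c(0, 100), 100, c(FALSE, FALSE))
  expect_equal(nrow(prediction_time(p3, ann_df(it_onset = 150, ictal_onset = 180))), 0)
})
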