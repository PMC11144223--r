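test_that("threshold selection matches the exhaustive scan oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:120, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.6)))
    probs <- round(runif(n), sample(1:3, 1))  # ties are common
    expect_equal(select_threshold(probs, labels),
                 brute_force_threshold(probs, labels))
  }
})

test_that("perfectly separated scores give the largest threshold with P=R=1", {
  probs <- c(rep(0.9, 5), rep(0.1, 5))
  labels <- c(rep(1, 5), rep(0, 5))
  expect_equal(select_threshold(probs, labels), 0.9)
  # spec-style 4-score instance, checked against the scan oracle
  probs <- c(0.8, 0.6, 0.7, 0.2)
  labels <- c(1, 1, 0, 0)
  expect_equal(select_threshold(probs, labels),
               brute_force_threshold(probs, labels))
  expect_error(select_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("symmetric equal-size classes meet precision = recall at the middle", {
  probs <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 0, 1, 1, 1, 1)
  th <- select_threshold(probs, labels)
  tp <- sum(probs >= th & labels == 1)
  fp <- sum(probs >= th & labels == 0)
  expect_equal(tp / (tp + fp), tp / sum(labels))
})

test_that("sleep time is the count of sleep-classified strides", {
  st <- estimate_sleep_time(rep(0.9, 960), stride_s = 15)
  expect_equal(st$total_sleep_h, 4)
  st <- estimate_sleep_time(rep(0.1, 100))
  expect_equal(st$total_sleep_h, 0)
  expect_error(estimate_sleep_time(numeric(0)), "no sleep prob")
})

test_that("ratio-to-AHI regression recovers exact linear data", {
  ahis <- c(2, 8, 20, 40, 4, 12, 25, 33)
  ratios <- ahis / 100
  fit <- fit_ahi_regression(ratios, ahis)
  expect_equal(fit$slope, 100, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_error(fit_ahi_regression(rep(0.3, 5), 1:5), "degenerate")
})

test_that("class weights equal the inverse class count", {
  set.seed(5)
  # balanced classes: weighted fit equals ordinary least squares
  ahis <- c(1, 3, 7, 12, 17, 22, 35, 44)
  ratios <- ahis / 80 + rnorm(8, 0, 0.01)
  fit_w <- fit_ahi_regression(ratios, ahis)
  fit_u <- stats::lm(ahis ~ ratios)
  expect_equal(fit_w$slope, unname(coef(fit_u)[2]))
  expect_equal(fit_w$intercept, unname(coef(fit_u)[1]))

  # duplicated severe patients: weighted fit equals the de-duplicated
  # unweighted fit (closed-form weighted least squares oracle)
  ahis2 <- c(ahis, rep(44, 3))
  ratios2 <- c(ratios, rep(ratios[8], 3))
  fit_dup <- fit_ahi_regression(ratios2, ahis2)
  w <- rep(1, 12)
  cls <- severity_class(ahis2)
  w <- 1 / as.numeric(table(cls)[cls])
  X <- cbind(1, ratios2)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * ahis2))
  expect_equal(fit_dup$intercept, beta[1], tolerance = 1e-9)
  expect_equal(fit_dup$slope, beta[2], tolerance = 1e-9)
})

test_that("AHI prediction is clipped at zero and monotone in the ratio", {
  calib <- list(slope = 100, intercept = 0)
  expect_equal(predict_ahi(calib, 0.2), 20)
  expect_equal(predict_ahi(list(slope = 50, intercept = -10), 0.1), 0)
  r <- seq(0, 1, by = 0.05)
  expect_true(all(diff(predict_ahi(list(slope = 72, intercept = -3), r)) >= 0))
})

test_that("severity classes use left-closed AASM boundaries", {
  expect_equal(severity_class(c(0, 4.9, 5, 14.9, 15, 29.9, 30, 31, 100)),
               c("healthy", "healthy", "mild", "mild", "moderate", "moderate",
                 "severe", "severe", "severe"))
  expect_error(severity_class(-1), "non-negative")
})

test_that("night segmentation merges consecutive event steps", {
  probs <- c(0.1, 0.9, 0.9, 0.9, 0.1, 0.1)
  seg <- segment_night(probs, rep(TRUE, 6), event_threshold = 0.5)
  expect_equal(seg$timeline,
               c("normal", "event", "event", "event", "normal", "normal"))
  # 3 consecutive positive steps: [15, 45+30) = one 60 s interval
  expect_equal(nrow(seg$events), 1)
  expect_equal(seg$events$end_s - seg$events$start_s, 60)

  all_awake <- segment_night(probs, rep(FALSE, 6), 0.5)
  expect_true(all(all_awake$timeline == "awake"))
  expect_equal(nrow(all_awake$events), 0)
  expect_error(segment_night(probs, TRUE, 0.5), "lengths differ")
})

test_that("the probability-level estimator assembles a consistent report", {
  calib <- calibration_model(0.5, slope = 100, intercept = 0)
  ev <- c(0.9, 0.9, 0.1, 0.1, 0.1, 0.2, 0.8, 0.1)
  sl <- c(0.9, 0.9, 0.9, 0.9, 0.2, 0.9, 0.9, 0.9)
  rep <- estimate_from_probs("pt1", ev, sl, calib)
  expect_equal(rep$n_sleep_windows, 7)
  expect_equal(rep$n_positive_windows, 3)
  expect_equal(rep$positive_ratio, 3 / 7)
  expect_equal(rep$ahi_estimate, 300 / 7)
  expect_equal(rep$severity, "severe")
  expect_equal(rep$positive_ratio,
               rep$n_positive_windows / rep$n_sleep_windows)

  none <- estimate_from_probs("pt2", ev, rep(0.1, 8), calib)
  expect_true(none$no_sleep)
  expect_equal(none$severity, "undetermined")
})
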