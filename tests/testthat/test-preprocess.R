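test_that("trimming removes the set-up margins and shifts annotations", {
  sim <- simulate_recording(quick_params(duration_h = 8, seed = 2,
                                         channel_rates = c(abdominal = 2)))
  rec <- trim_recording(sim$recording, 30)
  expect_equal(rec$duration_s, 420 * 60)
  expect_equal(length(rec$channels$abdominal$samples), 420 * 60 * 2)

  # identity trim
  expect_identical(trim_recording(sim$recording, 0), sim$recording)
  short <- simulate_recording(quick_params(duration_h = 0.5, seed = 1,
                                           channel_rates = c(abdominal = 2)))
  expect_error(trim_recording(short$recording, 30), "too short")

  # an event at t = 10 min is dropped; one spanning the boundary is clipped
  ann <- annotation_set(
    events = data.frame(type = c("apnea", "apnea"),
                        start_s = c(600, 29 * 60), duration_s = c(20, 120),
                        source_channel = "airflow"),
    sleep_stages = rep("sleep", 960), duration_s = 8 * 3600)
  tr <- trim_annotations(ann, 30, 8 * 3600)
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$start_s, 0)
  expect_equal(tr$events$duration_s, 60)
  expect_equal(length(tr$sleep_stages), 840)
  expect_equal(tr$duration_s, 420 * 60)
})

test_that("robust normalisation maps to [0,1] and shrugs off outliers", {
  set.seed(8)
  x <- rnorm(2000)
  out <- robust_normalize(x)
  expect_equal(range(out), c(0, 1))

  expect_equal(robust_normalize(rep(3.2, 50)), rep(0.5, 50))
  expect_error(robust_normalize(rep(NaN, 50)), "finite samples")
  expect_error(robust_normalize(c(1, 2, 3)), "at least 10")

  # one extreme outlier changes the non-outlier outputs by < 1%
  y <- x
  y[100] <- 1000 * max(abs(x))
  a <- robust_normalize(x)
  b <- robust_normalize(y)
  expect_lt(max(abs(a[-100] - b[-100])), 0.01)

  # idempotence up to the quantile-interpolation tolerance
  expect_lt(max(abs(robust_normalize(out) - out)), 0.005)
})

test_that("spline resampling reproduces knots, polynomials and sines", {
  set.seed(4)
  x <- rnorm(64)
  expect_identical(resample_signal(x, 8, 8), x)

  # upsampled signal passes through the original knots
  up <- resample_signal(x, 8, 16)
  expect_equal(up[seq(1, 127, by = 2)], x, tolerance = 1e-12)
  expect_equal(length(up), 128)

  # cubic splines reproduce linear ramps exactly
  ramp <- seq(0, 10, length.out = 50)
  up_r <- resample_signal(ramp, 5, 20)
  expect_equal(up_r, seq(0, by = ramp[2] / 4, length.out = 200),
               tolerance = 1e-9)

  # 0.25 Hz sine from 1 Hz to 64 Hz: error bounded by the cubic
  # interpolation floor at 4 knots per period (~0.02)
  t <- 0:120
  s <- resample_signal(sin(2 * pi * 0.25 * t), 1, 64)
  g <- (seq_along(s) - 1) / 64
  interior <- g <= 120  # beyond the last knot the spline extrapolates
  expect_lt(max(abs(s[interior] - sin(2 * pi * 0.25 * g[interior]))), 0.021)

  expect_error(resample_signal(c(1, 2, 3), 1, 4), "at least 4")
})

test_that("channel delay is a look-ahead shift with edge padding", {
  x <- rnorm(200)
  expect_identical(delay_channel(x, 2, 0), x)
  # impulse at t = 100 s seen at t = 90 s after a 10 s delay (2 Hz signal)
  imp <- rep(0, 400)
  imp[2 * 100 + 1] <- 1
  d <- delay_channel(imp, 2, 10)
  expect_equal(which(d == 1), 2 * 90 + 1)
  expect_equal(d[381:400], rep(imp[400], 20))
  expect_error(delay_channel(x, 2, 150), "signal duration")
})

test_that("the preprocessing chain emits aligned channels at the common rate", {
  sim <- simulate_recording(quick_params(duration_h = 0.5, sleep_fraction = 1,
                                         target_ahi = 8, seed = 6,
                                         channel_rates = c(abdominal = 10,
                                                           spo2 = 1,
                                                           ecg = 125)))
  pp <- preprocess_recording(
    sim$recording, channels = c("abdominal", "spo2"),
    config = preprocess_config(trim_min = 0, target_rate = 64,
                               spo2_delays = c(10, 15, 20, 25),
                               rri_enabled = TRUE))
  expect_equal(colnames(pp$signals),
               c("abdominal", "spo2", "spo2+10s", "spo2+15s", "spo2+20s",
                 "spo2+25s", "rri"))
  expect_equal(nrow(pp$signals), 0.5 * 3600 * 64)
  expect_equal(pp$rate, 64)
  expect_true(all(pp$signals >= 0 & pp$signals <= 1))
})

test_that("R peaks are recovered from clean synthetic ECG", {
  ecg <- synthetic_ecg(180, 125, 60)
  peaks <- detect_r_peaks(ecg$samples, 125)
  dist <- vapply(ecg$r_peaks,
                 function(p) min(abs(peaks - p)), numeric(1))
  expect_gte(mean(dist <= 0.04), 0.99)

  rri <- extract_rri(ecg$samples, 125, 64)
  expect_lt(max(abs(rri$rri - 1)), 1 / 125 + 1e-9)

  expect_error(detect_r_peaks(rep(0, 125 * 20) , 125), "no QRS")
  expect_error(detect_r_peaks(rnorm(125), 125), "at least 10 s")
})

test_that("RRI tracks a mid-record heart-rate step within 5 s", {
  ecg <- synthetic_ecg(240, 125, 60, hr2_bpm = 80, change_at_s = 120)
  rri <- extract_rri(ecg$samples, 125, 64)
  g <- (seq_along(rri$rri) - 1) / 64
  expect_equal(mean(rri$rri[g > 100 & g < 118]), 1.00, tolerance = 0.01)
  expect_equal(mean(rri$rri[g > 125 & g < 140]), 0.75, tolerance = 0.01)
})
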