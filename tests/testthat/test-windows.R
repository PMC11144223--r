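test_that("hypopnea subtype rules fire in the documented priority order", {
  ev <- list(start_s = 100, duration_s = 20)
  desat4 <- data.frame(start_s = 130, duration_s = 25, depth_percent = 4)
  desat2 <- data.frame(start_s = 130, duration_s = 25, depth_percent = 2)
  none_d <- desat4[0, ]
  arousal3 <- data.frame(start_s = 123, duration_s = 5)
  arousal20 <- data.frame(start_s = 140, duration_s = 5)
  none_a <- arousal3[0, ]

  expect_equal(classify_hypopnea(ev, desat4, none_a), "hypopnea1")
  expect_equal(classify_hypopnea(ev, none_d, arousal3), "hypopnea2")
  expect_equal(classify_hypopnea(ev, desat2, arousal20), "hypopnea3")
  # both rules hold: desaturation wins
  expect_equal(classify_hypopnea(ev, desat4, arousal3), "hypopnea1")
  # desaturation outside the 45 s window does not qualify
  late <- data.frame(start_s = 150, duration_s = 25, depth_percent = 4)
  expect_equal(classify_hypopnea(ev, late, none_a), "hypopnea3")
  # arousal exactly 5 s after the end qualifies; at the end itself it does not
  at5 <- data.frame(start_s = 125, duration_s = 5)
  at0 <- data.frame(start_s = 120, duration_s = 5)
  expect_equal(classify_hypopnea(ev, none_d, at5), "hypopnea2")
  expect_equal(classify_hypopnea(ev, none_d, at0), "hypopnea3")
})

test_that("derive_hypopnea_subtypes resolves plain hypopneas in place", {
  ann <- annotation_set(
    events = data.frame(type = c("apnea", "hypopnea"), start_s = c(10, 100),
                        duration_s = c(15, 20), source_channel = "airflow"),
    desaturations = data.frame(start_s = 120, duration_s = 25,
                               depth_percent = 3.5),
    sleep_stages = rep("sleep", 10), duration_s = 300)
  out <- derive_hypopnea_subtypes(ann)
  expect_equal(out$events$type, c("apnea", "hypopnea1"))
})

test_that("window counts and anchors follow the stride formula", {
  wd <- make_windows(NULL, window_s = 30, stride_s = 15, duration_s = 120)
  expect_equal(length(wd$anchors), 7)
  expect_equal(wd$anchors, seq(0, 90, by = 15))
  # enumeration oracle: count anchors whose window fits
  expect_equal(length(wd$anchors),
               sum((seq(0, 120, by = 15) + 30) <= 120))

  tiling <- make_windows(NULL, window_s = 30, stride_s = 30, duration_s = 120)
  expect_equal(tiling$anchors, c(0, 30, 60, 90))

  one <- make_windows(NULL, window_s = 30, stride_s = 15, duration_s = 30)
  expect_equal(length(one$anchors), 1)
  expect_error(make_windows(NULL, duration_s = 20), "shorter than one window")
})

test_that("event labels honour the overlap rule and exclude type-3 hypopneas", {
  stages <- rep("sleep", 4)
  mk_ann <- function(type) {
    annotation_set(events = data.frame(type = type, start_s = 70,
                                       duration_s = 15,
                                       source_channel = "airflow"),
                   sleep_stages = stages, duration_s = 120)
  }
  wd <- make_windows(NULL, duration_s = 120)
  lab <- label_windows(wd, mk_ann("apnea"))
  # apnea [70, 85) overlaps windows anchored 45..75 (>= 1 s each)
  expect_equal(which(lab$event_label == 1), c(4, 5, 6))
  expect_equal(sum(label_windows(wd, mk_ann("hypopnea3"))$event_label), 0)
  expect_equal(sum(label_windows(wd, mk_ann("hypopnea1"))$event_label), 3)

  # overlap threshold: a 1 s event overlapping by exactly 1 s counts
  ann1 <- annotation_set(events = data.frame(type = "apnea", start_s = 59,
                                             duration_s = 1,
                                             source_channel = "airflow"),
                         sleep_stages = stages, duration_s = 120)
  # [59, 60) overlaps [30, 60) and [45, 75) by exactly 1 s
  expect_equal(which(label_windows(wd, ann1)$event_label == 1), c(3, 4))
})

test_that("sleep labels follow the majority-epoch rule", {
  # epochs: awake, sleep, sleep, sleep -> window [15,45) is half awake
  ann <- annotation_set(sleep_stages = c("awake", "sleep", "sleep", "sleep"),
                        duration_s = 120)
  wd <- label_windows(make_windows(NULL, duration_s = 120), ann)
  # anchors 0,15,...,90: window [0,30) has 0 s sleep; [15,45) exactly 15 s
  expect_equal(wd$sleep_label, c(0, 1, 1, 1, 1, 1, 1))
})

test_that("balancing downsamples negatives deterministically", {
  wd <- make_windows(NULL, duration_s = 30 + 15 * 739)  # 740 windows
  wd$event_label <- c(rep(1L, 100), rep(0L, 640))
  wd$sleep_label <- rep(1L, 740)
  bal <- balance_dataset(wd, seed = 4)
  expect_equal(sum(bal$event_label == 1), 100)
  expect_equal(sum(bal$event_label == 0), 100)
  bal2 <- balance_dataset(wd, seed = 4)
  expect_identical(bal$anchors, bal2$anchors)

  wd$event_label <- rep(c(0L, 1L), length.out = 740)
  expect_equal(length(balance_dataset(wd, 1)$anchors), 740)
  wd$event_label <- rep(0L, 740)
  expect_error(balance_dataset(wd, 1), "nothing to balance")
})

test_that("labels depend only on annotations, not channel content", {
  sim <- simulate_recording(quick_params(duration_h = 0.5, sleep_fraction = 1,
                                         target_ahi = 10, seed = 21,
                                         channel_rates = c(abdominal = 4)))
  pp <- preprocess_recording(sim$recording, "abdominal",
                             preprocess_config(trim_min = 0, target_rate = 4,
                                               spo2_delays = numeric(0)))
  with_data <- label_windows(make_windows(pp), sim$annotations)
  anchors_only <- label_windows(make_windows(NULL, duration_s = pp$duration_s),
                                sim$annotations)
  expect_identical(with_data$event_label, anchors_only$event_label)
  expect_identical(with_data$sleep_label, anchors_only$sleep_label)
  # window array has the documented geometry
  expect_equal(dim(with_data$windows),
               c(length(with_data$anchors), 1, 30 * 4))
})
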