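# Synthetic polysomnography with planted, exactly known ground truth.
#
# Waveform models are deliberately simple fixtures: respiratory effort and
# airflow are amplitude-modulated ~0.25 Hz sinusoids, SpO2 is a piecewise
# linear desaturation/recovery profile around a 97% baseline, and the ECG
# is a train of Gaussian R-wave templates. They are the simplest signals
# that exercise every downstream detector, not physiological claims.

#' Parameters of the synthetic PSG generator
#'
#' Defaults describe a typical full-night home sleep study: 8 h in bed
#' with 75% of it asleep, a moderate target AHI, event durations of
#' 10-30 s, >=3% desaturations arriving 20 s after obstructive event
#' onset, and sensor rates matching common PSG hardware (effort and
#' airflow 10 Hz, pulse oximetry 1 Hz, ECG 125 Hz).
#'
#' @param duration_h Recording duration in hours.
#' @param sleep_fraction Fraction of the night spent asleep, in (0, 1].
#' @param target_ahi Planted AHI-event rate, events per hour of sleep.
#' @param event_mix Proportions over apnea / hypopnea1 / hypopnea2 /
#'   hypopnea3; must sum to 1. Type-3 hypopneas are planted on top of the
#'   AHI events and never count toward `target_ahi`.
#' @param event_duration_range Min/max event duration in seconds (min >= 10).
#' @param desat_depth SpO2 drop in percent for apneas and type-1
#'   hypopneas (>= 3).
#' @param desat_delay Seconds from event onset to desaturation onset
#'   (0-45).
#' @param heart_rate_bpm Constant heart rate of the ECG channel.
#' @param channel_rates Named sampling rates (Hz) for the channels to
#'   synthesise; any subset of abdominal, thoracic, airflow, spo2, ecg.
#' @param noise_sd Gaussian noise level on the unit-amplitude waveforms.
#' @param min_event_gap Minimum separation between consecutive events in
#'   seconds. The default keeps a desaturation planted for one event out
#'   of the 45 s association window of its neighbours (the
#'   constraint `desat_delay < min duration + gap` is validated), so
#'   hypopnea subtypes stay unambiguous.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(duration_h = 8,
                       sleep_fraction = 0.75,
                       target_ahi = 15,
                       event_mix = c(apnea = 0.4, hypopnea1 = 0.3,
                                     hypopnea2 = 0.15, hypopnea3 = 0.15),
                       event_duration_range = c(10, 30),
                       desat_depth = 4,
                       desat_delay = 20,
                       heart_rate_bpm = 60,
                       channel_rates = c(abdominal = 10, thoracic = 10,
                                         airflow = 10, spo2 = 1, ecg = 125),
                       noise_sd = 0.05,
                       min_event_gap = 30,
                       seed = 1L) {
  assert_that(duration_h > 0, "duration_h must be positive")
  assert_that(sleep_fraction > 0 && sleep_fraction <= 1,
              "sleep_fraction must lie in (0, 1]")
  assert_that(target_ahi >= 0, "target_ahi must be non-negative")
  assert_that(length(event_mix) == 4 && abs(sum(event_mix) - 1) < 1e-8,
              "event_mix must have 4 entries summing to 1")
  assert_that(all(event_mix >= 0), "event_mix proportions must be non-negative")
  assert_that(length(event_duration_range) == 2 &&
                event_duration_range[1] >= 10 &&
                diff(event_duration_range) >= 0,
              "event_duration_range must be (min >= 10 s, max >= min)")
  assert_that(desat_depth >= 3, "desat_depth must be >= 3 percent")
  assert_that(desat_delay >= 0 && desat_delay <= 45,
              "desat_delay must lie in [0, 45] s")
  assert_that(min_event_gap >= 10, "min_event_gap must be >= 10 s")
  # A desaturation must start before the next event's onset, otherwise it
  # could be attributed to the wrong hypopnea during subtype scoring.
  assert_that(desat_delay < event_duration_range[1] + min_event_gap,
              "desat_delay must be smaller than min event duration + min_event_gap")
  if (length(channel_rates)) {
    assert_that(!is.null(names(channel_rates)) && all(channel_rates > 0),
                "channel_rates must be a named vector of positive rates")
  }
  names(event_mix) <- c("apnea", "hypopnea1", "hypopnea2", "hypopnea3")
  structure(list(duration_h = duration_h, sleep_fraction = sleep_fraction,
                 target_ahi = target_ahi, event_mix = event_mix,
                 event_duration_range = event_duration_range,
                 desat_depth = desat_depth, desat_delay = desat_delay,
                 heart_rate_bpm = heart_rate_bpm,
                 channel_rates = channel_rates, noise_sd = noise_sd,
                 min_event_gap = min_event_gap, seed = as.integer(seed)),
            class = "sim_params")
}

# Integer counts per category matching proportions (largest remainder).
allocate_counts <- function(n, proportions) {
  raw <- n * proportions / sum(proportions)
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

# Sleep stage track: awake blocks at sleep onset, mid-night and offset.
plant_sleep_stages <- function(n_epochs, sleep_fraction) {
  n_awake <- round(n_epochs * (1 - sleep_fraction))
  stages <- rep("sleep", n_epochs)
  if (n_awake > 0) {
    a_on <- round(0.4 * n_awake)
    a_off <- round(0.4 * n_awake)
    a_mid <- n_awake - a_on - a_off
    if (a_on > 0) stages[seq_len(a_on)] <- "awake"
    if (a_off > 0) stages[(n_epochs - a_off + 1):n_epochs] <- "awake"
    if (a_mid > 0) {
      mid0 <- floor(n_epochs / 2) - floor(a_mid / 2)
      stages[mid0 + seq_len(a_mid)] <- "awake"
    }
  }
  stages
}

# Contiguous sleep intervals [start_s, end_s) from a 30 s epoch track.
sleep_segments <- function(stages, epoch_s = 30) {
  if (!length(stages)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  r <- rle(stages == "sleep")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_s = (starts[keep] - 1) * epoch_s, end_s = ends[keep] * epoch_s)
}

# Place events sequentially inside sleep segments with randomised gaps.
place_events <- function(durations, segments, min_gap) {
  n <- length(durations)
  starts <- numeric(n)
  seg_i <- 1L
  if (nrow(segments) == 0 && n > 0) {
    stop_validation("no sleep segments available to host events")
  }
  cursor <- if (nrow(segments)) segments$start_s[1] + stats::runif(1, 5, 15) else 0
  for (i in seq_len(n)) {
    gap <- min_gap + stats::runif(1, 0, 10)
    repeat {
      if (seg_i > nrow(segments)) {
        stop_validation("recording too short to host ", n,
                        " events at the requested AHI")
      }
      if (cursor + durations[i] <= segments$end_s[seg_i] - 2) break
      seg_i <- seg_i + 1L
      if (seg_i <= nrow(segments)) {
        cursor <- segments$start_s[seg_i] + stats::runif(1, 5, 15)
      }
    }
    starts[i] <- cursor
    cursor <- cursor + durations[i] + gap
  }
  starts
}

# Event amplitude factors relative to quiet-sleep breathing.
EFFORT_AMP <- c(sleep = 1, awake = 1.8, apnea = 0.2, hypopnea = 0.55)
AIRFLOW_AMP <- c(sleep = 1, awake = 1.3, apnea = 0.05, hypopnea = 0.5)

# Per-sample amplitude envelope for a breathing-derived channel.
breathing_envelope <- function(n, rate, stages, events, amp) {
  env <- rep(amp[["sleep"]], n)
  if (any(stages == "awake")) {
    awake <- which(stages == "awake")
    for (e in awake) {
      i0 <- round((e - 1) * 30 * rate) + 1
      i1 <- min(n, round(e * 30 * rate))
      env[i0:i1] <- amp[["awake"]]
    }
  }
  if (nrow(events)) {
    fac <- ifelse(events$type == "apnea", amp[["apnea"]], amp[["hypopnea"]])
    for (k in seq_len(nrow(events))) {
      i0 <- round(events$start_s[k] * rate) + 1
      i1 <- min(n, round((events$start_s[k] + events$duration_s[k]) * rate))
      if (i0 <= i1) env[i0:i1] <- fac[k]
    }
  }
  env
}

#' Synthetic single-lead ECG with known R-peak times
#'
#' Gaussian R-wave templates on a flat baseline. The heart rate may step
#' once mid-record to exercise RR-interval tracking.
#'
#' @param duration_s Signal length in seconds.
#' @param rate Sampling rate in Hz.
#' @param hr_bpm Heart rate in beats/min.
#' @param hr2_bpm,change_at_s Optional second rate taking over at
#'   `change_at_s` seconds.
#' @param noise_sd Additive Gaussian noise SD (template peak height is 1).
#' @return List with `samples` and the planted `r_peaks` (seconds).
#' @export
synthetic_ecg <- function(duration_s, rate, hr_bpm = 60,
                          hr2_bpm = NULL, change_at_s = NULL,
                          noise_sd = 0.02) {
  n <- round(duration_s * rate)
  peaks <- numeric(0)
  t <- 0.3
  while (t < duration_s - 0.2) {
    peaks <- c(peaks, t)
    bpm <- if (!is.null(change_at_s) && t >= change_at_s) hr2_bpm else hr_bpm
    t <- t + 60 / bpm
  }
  x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  tt <- (seq_len(n) - 1) / rate
  half_w <- 0.06  # template support of +/- 60 ms
  for (p in peaks) {
    i0 <- max(1, floor((p - half_w) * rate) + 1)
    i1 <- min(n, ceiling((p + half_w) * rate) + 1)
    idx <- i0:i1
    x[idx] <- x[idx] + exp(-((tt[idx] - p)^2) / (2 * 0.012^2))
  }
  list(samples = x, r_peaks = peaks)
}

# SpO2 channel: 97% baseline, piecewise-linear desaturation profiles.
spo2_signal <- function(n, rate, stages, desaturations, noise_sd) {
  x <- 97 + stats::rnorm(n, 0, 4 * noise_sd)
  if (any(stages == "awake")) {  # movement artefact while awake
    for (e in which(stages == "awake")) {
      i0 <- round((e - 1) * 30 * rate) + 1
      i1 <- min(n, round(e * 30 * rate))
      x[i0:i1] <- x[i0:i1] + stats::rnorm(i1 - i0 + 1, 0, 8 * noise_sd)
    }
  }
  tt <- (seq_len(n) - 1) / rate
  for (k in seq_len(nrow(desaturations))) {
    s <- desaturations$start_s[k]
    d <- desaturations$depth_percent[k]
    t_fall <- 8; t_hold <- 5; t_rec <- 12
    drop <- stats::approx(
      x = s + c(0, t_fall, t_fall + t_hold, t_fall + t_hold + t_rec),
      y = c(0, -d, -d, 0), xout = tt, method = "linear", rule = 1
    )$y
    drop[is.na(drop)] <- 0
    x <- x + drop
  }
  pmin(100, x)
}

#' Simulate one synthetic sleep recording with ground truth
#'
#' Plants apnea/hypopnea events inside sleep epochs (never while awake,
#' separated by at least `min_event_gap` seconds of normal breathing),
#' desaturations `desat_delay` seconds after apnea and type-1 hypopnea
#' onsets, arousals within 5 s after type-2 hypopnea ends, and an awake /
#' sleep stage track with contiguous awake blocks. During apneas the
#' airflow amplitude collapses by more than 90% (effort also drops);
#' during hypopneas airflow drops by more than 30% but at most 90%.
#'
#' @param params A [sim_params()] object.
#' @param patient_id Identifier stored in the recording.
#' @param signals If `FALSE`, skip waveform synthesis and return only the
#'   annotations and ground truth (fast path for label-level studies);
#'   the recording then carries an empty channel list.
#' @return List with `recording`, `annotations` (an [annotation_set()]),
#'   and `truth` (events, arousals, desaturations, sleep stages, R-peak
#'   times, planted AHI and sleep hours).
#' @export
simulate_recording <- function(params = sim_params(), patient_id = "S0001",
                               signals = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    duration_s <- params$duration_h * 3600
    n_epochs <- floor(duration_s / 30)
    stages <- plant_sleep_stages(n_epochs, params$sleep_fraction)
    sleep_h <- sum(stages == "sleep") * 30 / 3600
    segs <- sleep_segments(stages)

    n_ahi <- round(params$target_ahi * sleep_h)
    ahi_mix <- params$event_mix[1:3]
    if (n_ahi > 0 && sum(ahi_mix) == 0) {
      stop_validation("target_ahi > 0 but event_mix assigns no AHI-event types")
    }
    n_by_type <- if (n_ahi > 0) allocate_counts(n_ahi, ahi_mix) else c(0L, 0L, 0L)
    p3 <- params$event_mix[["hypopnea3"]]
    n_h3 <- if (p3 > 0 && p3 < 1) round(n_ahi * p3 / (1 - p3)) else 0L
    types <- rep(c("apnea", "hypopnea1", "hypopnea2", "hypopnea3"),
                 times = c(n_by_type, n_h3))
    n_tot <- length(types)
    types <- if (n_tot) sample(types) else character(0)
    durations <- stats::runif(n_tot, params$event_duration_range[1],
                              params$event_duration_range[2])
    starts <- place_events(durations, segs, params$min_event_gap)
    ord <- order(starts)
    events <- data.frame(type = types[ord], start_s = starts[ord],
                         duration_s = durations[ord],
                         source_channel = rep("airflow", n_tot),
                         stringsAsFactors = FALSE)

    with_desat <- events$type %in% c("apnea", "hypopnea1")
    desaturations <- data.frame(
      start_s = events$start_s[with_desat] + params$desat_delay,
      duration_s = rep(25, sum(with_desat)),
      depth_percent = rep(params$desat_depth, sum(with_desat))
    )
    desaturations <- desaturations[desaturations$start_s < duration_s - 5, ,
                                   drop = FALSE]
    h2 <- events$type == "hypopnea2"
    arousals <- data.frame(
      start_s = events$start_s[h2] + events$duration_s[h2] + 1 +
        stats::runif(sum(h2), 0, 2),
      duration_s = rep(5, sum(h2))
    )

    truth <- list(events = events[, c("type", "start_s", "duration_s")],
                  arousals = arousals,
                  desaturations = desaturations,
                  sleep_stages = stages,
                  r_peaks = numeric(0),
                  planted_ahi = if (sleep_h > 0) n_ahi / sleep_h else 0,
                  sleep_h = sleep_h)

    channels <- list()
    if (signals && length(params$channel_rates)) {
      for (ch in names(params$channel_rates)) {
        rate <- params$channel_rates[[ch]]
        n <- round(duration_s * rate)
        tt <- (seq_len(n) - 1) / rate
        samples <- switch(
          ch,
          abdominal = ,
          thoracic = {
            amp <- breathing_envelope(n, rate, stages, events, EFFORT_AMP)
            phase <- if (ch == "thoracic") 0.6 else 0
            scale <- if (ch == "thoracic") 0.9 else 1
            scale * amp * sin(2 * pi * 0.25 * tt + phase) +
              stats::rnorm(n, 0, params$noise_sd)
          },
          airflow = {
            amp <- breathing_envelope(n, rate, stages, events, AIRFLOW_AMP)
            amp * sin(2 * pi * 0.25 * tt + 0.3) +
              stats::rnorm(n, 0, params$noise_sd / 2)
          },
          spo2 = spo2_signal(n, rate, stages, desaturations, params$noise_sd),
          ecg = {
            ecg <- synthetic_ecg(duration_s, rate, params$heart_rate_bpm,
                                 noise_sd = params$noise_sd / 2)
            truth$r_peaks <- ecg$r_peaks
            ecg$samples
          },
          stop_validation("unknown channel in channel_rates: ", ch)
        )
        unit <- switch(ch, spo2 = "%", ecg = "mV", "au")
        channels[[ch]] <- list(samples = samples, rate = rate,
                               physical_unit = unit)
      }
    }

    recording <- new_recording(patient_id, channels, duration_s)
    annotations <- annotation_set(
      events = events,
      arousals = arousals,
      desaturations = desaturations,
      sleep_stages = stages,
      duration_s = duration_s
    )
    list(recording = recording, annotations = annotations, truth = truth)
  })
}

#' Simulate a cohort spanning the four AHI severity bands
#'
#' Patient counts per band follow `severity_distribution` (largest
#' remainder rounding); each patient's target AHI is drawn uniformly
#' inside its band (healthy <5, mild 5-15, moderate 15-30, severe 30-45
#' events/h) and each patient gets a seed derived deterministically from
#' the cohort seed.
#'
#' @param n_patients Number of patients (>= 1).
#' @param severity_distribution Proportions over
#'   healthy/mild/moderate/severe, summing to 1.
#' @param seed Cohort seed.
#' @param base_params A [sim_params()] template; its `target_ahi` and
#'   `seed` are overridden per patient.
#' @param signals Passed to [simulate_recording()].
#' @return List of per-patient lists (`recording`, `annotations`,
#'   `truth`, `target_ahi`, `severity`).
#' @export
simulate_cohort <- function(n_patients,
                            severity_distribution = c(healthy = 0.25, mild = 0.25,
                                                      moderate = 0.25, severe = 0.25),
                            seed = 1L,
                            base_params = sim_params(),
                            signals = TRUE) {
  assert_that(is_count(n_patients) && n_patients >= 1,
              "n_patients must be a positive integer")
  assert_that(length(severity_distribution) == 4 &&
                abs(sum(severity_distribution) - 1) < 1e-8,
              "severity_distribution must have 4 proportions summing to 1")
  counts <- allocate_counts(n_patients, severity_distribution)
  bands <- list(healthy = c(0, 5), mild = c(5, 15),
                moderate = c(15, 30), severe = c(30, 45))
  classes <- rep(SEVERITY_LEVELS, times = counts)
  # planted_ahi is quantized to whole events per sleep time; draw the
  # target half a quantization step inside the band so the planted value
  # provably stays in its severity class
  n_epochs <- floor(base_params$duration_h * 3600 / 30)
  sleep_h <- (n_epochs - round(n_epochs * (1 - base_params$sleep_fraction))) *
    30 / 3600
  margin <- 1 / (2 * sleep_h)
  ahis <- with_seed(seed, {
    unlist(lapply(seq_len(n_patients), function(i) {
      b <- bands[[classes[i]]]
      lo <- if (b[1] > 0) b[1] + margin else 0
      hi <- max(lo, b[2] - margin)
      stats::runif(1, lo, hi)
    }))
  })
  lapply(seq_len(n_patients), function(i) {
    p <- base_params
    p$target_ahi <- ahis[i]
    p$seed <- derive_seed(seed, i)
    pid <- sprintf("P%04d", i)
    out <- simulate_recording(p, patient_id = pid, signals = signals)
    out$target_ahi <- ahis[i]
    out$severity <- classes[i]
    out
  })
}
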