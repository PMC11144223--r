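# Per-channel signal conditioning: setup-time trimming, outlier-robust
# normalisation, cubic-spline resampling to a common rate, SpO2 delay
# variants, and pipeline orchestration.

#' Preprocessing configuration
#'
#' @param trim_min Minutes removed from each end of the recording
#'   (sensor set-up time).
#' @param target_rate Common sampling rate all channels are brought to,
#'   in Hz (the maximum rate across the supported sensors).
#' @param central_fraction Fraction of data points whose statistics drive
#'   the normalisation (0.95 keeps percentiles 2.5-97.5).
#' @param spo2_delays Seconds of look-ahead appended as extra SpO2
#'   channels (the oximetry response lags the airflow obstruction).
#' @param rri_enabled Derive an RR-interval channel from the ECG.
#' @param normalize_after_resample Normalise after resampling (default)
#'   or before.
#' @export
preprocess_config <- function(trim_min = 30, target_rate = 64,
                              central_fraction = 0.95,
                              spo2_delays = c(10, 15, 20, 25),
                              rri_enabled = FALSE,
                              normalize_after_resample = TRUE) {
  assert_that(central_fraction > 0 && central_fraction <= 1,
              "central_fraction must lie in (0, 1]")
  assert_that(target_rate > 0, "target_rate must be positive")
  assert_that(all(spo2_delays >= 0), "spo2_delays must be non-negative")
  list(trim_min = trim_min, target_rate = target_rate,
       central_fraction = central_fraction, spo2_delays = spo2_delays,
       rri_enabled = rri_enabled,
       normalize_after_resample = normalize_after_resample)
}

#' Remove set-up time from both ends of a recording
#'
#' @param recording A `psg_recording` longer than `2 * trim_min`.
#' @param trim_min Minutes to drop from each end.
#' @return The trimmed recording; its time base starts at the old
#'   `trim_min` mark.
#' @export
trim_recording <- function(recording, trim_min = 30) {
  trim_s <- trim_min * 60
  if (recording$duration_s <= 2 * trim_s) {
    stop_validation("recording too short: ", recording$duration_s,
                    " s <= 2 x ", trim_s, " s trim")
  }
  if (trim_min == 0) return(recording)
  new_dur <- recording$duration_s - 2 * trim_s
  channels <- lapply(recording$channels, function(ch) {
    i0 <- round(trim_s * ch$rate) + 1
    i1 <- round(trim_s * ch$rate) + round(new_dur * ch$rate)
    ch$samples <- ch$samples[i0:i1]
    ch
  })
  new_recording(recording$patient_id, channels, new_dur,
                start_time = recording$start_time + trim_s)
}

#' Shift annotations onto the trimmed time base
#'
#' Events, arousals and desaturations are shifted by `-trim_min`;
#' anything fully outside the retained interval is dropped and boundary
#' intervals are clipped. Sleep-stage epochs falling in the trimmed
#' margins are removed.
#'
#' @param annotations An [annotation_set()].
#' @param trim_min Minutes trimmed from each end.
#' @param duration_s Original recording duration in seconds.
#' @export
trim_annotations <- function(annotations, trim_min, duration_s) {
  trim_s <- trim_min * 60
  if (trim_min == 0) return(annotations)
  new_dur <- duration_s - 2 * trim_s
  assert_that(new_dur > 0, "recording too short for the requested trim")
  clip <- function(df) {
    if (!nrow(df)) return(df)
    start <- df$start_s - trim_s
    end <- start + df$duration_s
    keep <- end > 0 & start < new_dur
    df <- df[keep, , drop = FALSE]
    start <- pmax(0, start[keep])
    end <- pmin(new_dur, end[keep])
    df$start_s <- start
    df$duration_s <- end - start
    df
  }
  n_epoch_trim <- trim_s %/% 30
  stages <- annotations$sleep_stages
  if (length(stages) > 2 * n_epoch_trim) {
    stages <- stages[(n_epoch_trim + 1):(length(stages) - n_epoch_trim)]
    stages <- stages[seq_len(min(length(stages), floor(new_dur / 30)))]
  } else {
    stages <- character(0)
  }
  annotation_set(events = clip(annotations$events),
                 arousals = clip(annotations$arousals),
                 desaturations = clip(annotations$desaturations),
                 sleep_stages = stages, duration_s = new_dur)
}

#' Outlier-robust normalisation to \[0, 1\]
#'
#' Mean and SD are computed over the central `central_fraction` of the
#' data (percentile band), values are clipped to that band, z-scored with
#' the robust statistics and min-max mapped to \[0, 1\]. This removes the
#' bias a single extreme artefact would otherwise impose on plain min-max
#' scaling. A constant signal maps to all 0.5.
#'
#' @param samples Numeric vector with at least 10 finite values.
#' @param central_fraction Central probability mass used for the
#'   statistics.
#' @export
robust_normalize <- function(samples, central_fraction = 0.95) {
  finite <- samples[is.finite(samples)]
  if (length(finite) < 10) {
    stop_validation("robust_normalize needs at least 10 finite samples")
  }
  alpha <- (1 - central_fraction) / 2
  band <- stats::quantile(finite, c(alpha, 1 - alpha), names = FALSE)
  central <- finite[finite >= band[1] & finite <= band[2]]
  mu <- mean(central)
  s <- stats::sd(central)
  if (!is.finite(s) || s == 0 || band[1] == band[2]) {
    return(rep(0.5, length(samples)))
  }
  z <- (pmin(pmax(samples, band[1]), band[2]) - mu) / s
  zr <- range(z, na.rm = TRUE)
  (z - zr[1]) / (zr[2] - zr[1])
}

#' Resample a signal with a natural cubic spline
#'
#' Fits a natural cubic spline through the input samples and evaluates it
#' on the uniform target grid spanning the same duration; cubic
#' interpolation preserves the higher-frequency content that linear
#' interpolation would attenuate.
#'
#' @param samples Input samples (>= 4, cubic support).
#' @param rate_in,target_rate Input and output rates in Hz.
#' @return Samples at `target_rate`, length `round(duration * target_rate)`.
#' @export
resample_signal <- function(samples, rate_in, target_rate) {
  assert_that(rate_in > 0 && target_rate > 0, "rates must be positive")
  n <- length(samples)
  if (n < 4) stop_validation("resampling needs at least 4 samples")
  if (rate_in == target_rate) return(samples)
  duration <- n / rate_in
  n_out <- round(duration * target_rate)
  times <- (seq_len(n) - 1) / rate_in
  grid <- (seq_len(n_out) - 1) / target_rate
  stats::spline(times, samples, xout = grid, method = "natural")$y
}

#' Shift a channel so each time point sees the signal `delay_s` later
#'
#' `out[t] = in[t + delay_s]`: a window anchored at `t` then sees the
#' delayed oximetry response to an obstruction at `t`. The trailing
#' `delay_s` seconds are padded by edge-value extension.
#'
#' @param samples Input samples.
#' @param rate Sampling rate in Hz.
#' @param delay_s Look-ahead in seconds (0 = identity).
#' @export
delay_channel <- function(samples, rate, delay_s) {
  assert_that(delay_s >= 0, "delay_s must be non-negative")
  n <- length(samples)
  k <- round(delay_s * rate)
  if (k >= n) stop_validation("delay of ", delay_s, " s >= signal duration")
  if (k == 0) return(samples)
  c(samples[(k + 1):n], rep(samples[n], k))
}

#' Run the full preprocessing chain on a recording
#'
#' Trims set-up time, resamples every selected channel to the common
#' rate with the cubic spline, applies the robust normalisation,
#' optionally derives the RR-interval channel from the ECG, and appends
#' the delayed SpO2 variants as separate channels (named `spo2+10s`,
#' ...). All returned channels share one rate and length.
#'
#' @param recording A `psg_recording`.
#' @param channels Channels to keep (default: all present except the
#'   ECG, which only enters through the RRI).
#' @param config A [preprocess_config()].
#' @return List with `signals` (matrix, time x channel), `rate`,
#'   `duration_s`, `patient_id`.
#' @export
preprocess_recording <- function(recording,
                                 channels = setdiff(names(recording$channels), "ecg"),
                                 config = preprocess_config()) {
  rec <- trim_recording(recording, config$trim_min)
  out <- list()
  for (nm in channels) {
    ch <- rec$channels[[nm]]
    if (is.null(ch)) stop_validation("channel not present: ", nm)
    x <- ch$samples
    if (config$normalize_after_resample) {
      x <- resample_signal(x, ch$rate, config$target_rate)
      x <- robust_normalize(x, config$central_fraction)
    } else {
      x <- robust_normalize(x, config$central_fraction)
      x <- resample_signal(x, ch$rate, config$target_rate)
    }
    out[[nm]] <- x
    if (nm == "spo2" && length(config$spo2_delays)) {
      for (d in config$spo2_delays) {
        out[[sprintf("spo2+%gs", d)]] <- delay_channel(x, config$target_rate, d)
      }
    }
  }
  if (config$rri_enabled) {
    ecg <- rec$channels[["ecg"]]
    if (is.null(ecg)) stop_validation("rri_enabled but no ecg channel present")
    rri <- extract_rri(ecg$samples, ecg$rate, target_rate = config$target_rate)
    out[["rri"]] <- robust_normalize(rri$rri, config$central_fraction)
  }
  lens <- vapply(out, length, integer(1))
  assert_that(length(unique(lens)) == 1L,
              "preprocessed channels differ in length: ",
              paste(lens, collapse = ", "))
  list(signals = do.call(cbind, out), rate = config$target_rate,
       duration_s = rec$duration_s, patient_id = rec$patient_id)
}
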