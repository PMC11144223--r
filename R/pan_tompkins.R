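# Pan-Tompkins QRS detection and RR-interval series extraction.
#
# The classic chain — band-pass around the QRS energy band, derivative,
# squaring, moving-window integration, adaptive dual thresholds with
# search-back and a 200 ms refractory period — with the filter constants
# derived from the working sampling rate rather than the original 200 Hz
# design. Filtering is zero-phase, so detected peaks need no group-delay
# correction.

#' Detect R-peak times in an ECG signal
#'
#' @param ecg_samples Raw ECG samples.
#' @param rate Sampling rate in Hz (>= 60).
#' @return R-peak times in seconds from signal start.
#' @export
detect_r_peaks <- function(ecg_samples, rate) {
  assert_that(rate >= 60, "ECG rate must be >= 60 Hz")
  n <- length(ecg_samples)
  assert_that(n / rate >= 10, "ECG must be at least 10 s long")

  # 1. band-pass ~5-15 Hz, zero phase
  bf <- signal::butter(2, c(5, 15) / (rate / 2), type = "pass")
  bp <- signal::filtfilt(bf, ecg_samples - mean(ecg_samples))
  # 2. five-point derivative
  dv <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  dv[is.na(dv)] <- 0
  # 3. squaring
  sq <- as.numeric(dv)^2
  # 4. moving-window integration, ~150 ms, centred
  N <- max(3L, round(0.15 * rate))
  if (N %% 2 == 0) N <- N + 1L
  mwi <- stats::filter(sq, rep(1 / N, N), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate peaks: local maxima of the integrated signal
  is_peak <- c(FALSE, diff(mwi) > 0) & c(mwi[-n] >= mwi[-1], FALSE)
  cand <- which(is_peak)
  if (!length(cand)) stop("no QRS found")

  refractory <- 0.2 * rate
  init_n <- min(n, round(2 * rate))
  spki <- max(mwi[seq_len(init_n)]) * 0.5
  npki <- mean(mwi[seq_len(init_n)]) * 0.5
  peaks <- integer(0)
  rr_hist <- numeric(0)
  last_cand_idx <- 0L

  accept <- function(i) {
    peaks <<- c(peaks, i)
    if (length(peaks) >= 2) {
      rr <- diff(utils::tail(peaks, 2))
      rr_hist <<- utils::tail(c(rr_hist, rr), 8)
    }
  }

  for (ci in seq_along(cand)) {
    i <- cand[ci]
    thr1 <- npki + 0.25 * (spki - npki)
    if (length(peaks) && (i - peaks[length(peaks)]) < refractory) next
    if (mwi[i] > thr1) {
      spki <- 0.125 * mwi[i] + 0.875 * spki
      accept(i)
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
      # search-back: no beat for > 1.66 x average RR
      if (length(rr_hist) && length(peaks)) {
        since <- i - peaks[length(peaks)]
        if (since > 1.66 * mean(rr_hist)) {
          win <- cand[cand > peaks[length(peaks)] + refractory & cand <= i]
          if (length(win)) {
            j <- win[which.max(mwi[win])]
            if (mwi[j] > 0.5 * thr1) {
              spki <- 0.25 * mwi[j] + 0.75 * spki
              accept(j)
            }
          }
        }
      }
    }
    last_cand_idx <- i
  }
  if (!length(peaks)) stop("no QRS found")

  # refine each detection to the raw-signal maximum within +/- 100 ms
  half <- round(0.1 * rate)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(ecg_samples[lo:hi]) - 1L)
  }, integer(1))
  (sort(unique(refined)) - 1) / rate
}

#' RR-interval series as a uniformly sampled signal
#'
#' Runs [detect_r_peaks()] and converts the beat-to-beat interval series
#' to a uniform signal at `target_rate`. With step interpolation
#' (default) the value at time t is the most recently completed RR
#' interval; `interp = "spline"` fits a cubic through the beat times.
#'
#' @param ecg_samples Raw ECG samples (>= 10 s).
#' @param rate ECG sampling rate in Hz.
#' @param target_rate Output rate in Hz.
#' @param interp `"step"` or `"spline"`.
#' @return List with `rri` (seconds, uniform at `target_rate`), `rate`,
#'   and the detected `r_peaks` (seconds).
#' @export
extract_rri <- function(ecg_samples, rate, target_rate = 64,
                        interp = c("step", "spline")) {
  interp <- match.arg(interp)
  peaks <- detect_r_peaks(ecg_samples, rate)
  if (length(peaks) < 2) stop("no QRS found")
  rr <- diff(peaks)
  duration <- length(ecg_samples) / rate
  grid <- (seq_len(round(duration * target_rate)) - 1) / target_rate
  rri <- if (interp == "step") {
    stats::approx(peaks[-1], rr, xout = grid, method = "constant",
                  f = 0, rule = 2)$y
  } else {
    if (length(rr) < 4) stop_validation("spline interpolation needs >= 4 intervals")
    stats::spline(peaks[-1], rr, xout = grid, method = "natural")$y
  }
  list(rri = rri, rate = target_rate, r_peaks = peaks)
}
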