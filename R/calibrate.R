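#' Choose the event-probability threshold where precision equals recall
#'
#' Scans all distinct predicted probabilities (plus 0 and 1) as candidate
#' thresholds with the decision rule `prob >= threshold`, and returns the
#' candidate minimising |precision - recall| on the supplied validation
#' scores. Ties are broken toward the higher threshold, i.e. the lower
#' positive-call rate.
#'
#' @param probabilities Predicted event probabilities on validation windows.
#' @param labels Binary 0/1 window labels.
#' @return A single threshold in \[0, 1\].
#' @export
select_threshold <- function(probabilities, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(probabilities) == length(labels))
  candidates <- sort(unique(c(0, 1, probabilities)), decreasing = TRUE)
  best <- NA_real_; best_gap <- Inf; best_prec <- -Inf
  n_pos <- sum(labels == 1L)
  for (th in candidates) {  # decreasing: first optimum found is the largest
    pred <- probabilities >= th
    tp <- sum(pred & labels == 1L)
    fp <- sum(pred & labels == 0L)
    if (tp + fp == 0 || tp == 0) next  # precision undefined or P=R=0 trivially
    precision <- tp / (tp + fp)
    recall <- tp / n_pos
    gap <- abs(precision - recall)
    if (gap < best_gap - 1e-12 ||
        (abs(gap - best_gap) <= 1e-12 && precision > best_prec + 1e-12)) {
      best_gap <- gap
      best_prec <- precision
      best <- th
    }
  }
  if (is.na(best)) stop_validation("no usable threshold candidate")
  best
}

#' Total sleep time from per-window sleep probabilities
#'
#' Each stride step whose window is classified as sleep (probability >=
#' `threshold`, default 0.5) contributes `stride_s` seconds of sleep.
#'
#' @param sleep_probs One probability per window.
#' @param stride_s Stride between window anchors in seconds.
#' @param threshold Sleep/awake decision threshold.
#' @return List with `total_sleep_h` and logical `sleep_mask`.
#' @export
estimate_sleep_time <- function(sleep_probs, stride_s = 15, threshold = 0.5) {
  if (length(sleep_probs) == 0) stop_validation("no sleep probabilities supplied")
  mask <- sleep_probs >= threshold
  list(total_sleep_h = sum(mask) * stride_s / 3600, sleep_mask = mask)
}

#' Fit the positive-ratio to AHI calibration regression
#'
#' Weighted least squares of true AHI on the per-patient positive-window
#' ratio. Each patient is weighted by the inverse of the size of its
#' severity class in the fitting set, so sparse classes are not swamped by
#' abundant ones.
#'
#' @param ratios Per-patient fraction of sleep windows classified
#'   event-positive.
#' @param true_ahis Reference AHI per patient (events per hour of sleep).
#' @param severities Severity class per patient; defaults to the class of
#'   `true_ahis` under [severity_class()].
#' @return List with `slope` and `intercept`.
#' @export
fit_ahi_regression <- function(ratios, true_ahis,
                               severities = severity_class(true_ahis)) {
  stopifnot(length(ratios) == length(true_ahis),
            length(severities) == length(ratios))
  if (length(unique(ratios)) < 2L) {
    stop_validation("degenerate regression: all ratios identical")
  }
  severities <- as.character(severities)
  class_n <- table(severities)
  w <- 1 / as.numeric(class_n[severities])
  fit <- stats::lm(true_ahis ~ ratios, weights = w)
  coefs <- stats::coef(fit)
  if (any(!is.finite(coefs))) stop_validation("regression coefficients not finite")
  list(slope = unname(coefs[2]), intercept = unname(coefs[1]))
}

#' Map a positive-window ratio to an AHI estimate
#'
#' Applies the calibration line and clips negative extrapolations at 0.
#'
#' @param calib A calibration model (list with `slope`, `intercept`),
#'   e.g. from [fit_ahi_regression()] or [calibration_model()].
#' @param positive_ratio Fraction of sleep windows classified positive.
#' @export
predict_ahi <- function(calib, positive_ratio) {
  pmax(0, calib$slope * positive_ratio + calib$intercept)
}

#' AASM severity class from an AHI value
#'
#' healthy: AHI < 5; mild: 5 <= AHI < 15; moderate: 15 <= AHI < 30;
#' severe: AHI >= 30. Boundaries are left-closed.
#'
#' @param ahi Non-negative AHI value(s), events per hour of sleep.
#' @return Character vector over healthy/mild/moderate/severe.
#' @export
severity_class <- function(ahi) {
  if (any(!is.finite(ahi)) || any(ahi < 0)) {
    stop_validation("AHI must be non-negative and finite")
  }
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = SEVERITY_LEVELS) |> as.character()
}

#' Bundle classifier thresholds and regression coefficients
#'
#' @param event_threshold Probability threshold for calling an AHI-event
#'   window (fit with [select_threshold()]).
#' @param slope,intercept Ratio-to-AHI regression coefficients.
#' @param sleep_threshold Sleep/awake probability threshold (0.5 by
#'   convention).
#' @export
calibration_model <- function(event_threshold, slope, intercept,
                              sleep_threshold = 0.5) {
  assert_that(event_threshold > 0 && event_threshold < 1,
              "event_threshold must lie in (0, 1)")
  assert_that(sleep_threshold > 0 && sleep_threshold < 1,
              "sleep_threshold must lie in (0, 1)")
  assert_that(is.finite(slope), "slope must be finite")
  structure(list(event_threshold = event_threshold,
                 sleep_threshold = sleep_threshold,
                 slope = slope, intercept = intercept),
            class = "calibration_model")
}

#' Segment a night into awake / normal / event steps
#'
#' Each stride step is "awake" when its window is classified awake,
#' otherwise "event" when its event probability reaches the threshold,
#' otherwise "normal". Consecutive "event" steps are merged into
#' half-open intervals `[anchor, last_anchor + window_s)`.
#'
#' @param event_probs Per-window event probabilities.
#' @param sleep_mask Logical per-window sleep classification.
#' @param event_threshold Probability threshold for an event call.
#' @param stride_s,window_s Window geometry in seconds.
#' @return List with `timeline` (character per step), `anchors`, and
#'   `events` (data.frame start_s / end_s of merged detected intervals).
#' @export
segment_night <- function(event_probs, sleep_mask, event_threshold,
                          stride_s = 15, window_s = 30) {
  if (length(event_probs) != length(sleep_mask)) {
    stop_validation("event_probs and sleep_mask lengths differ")
  }
  anchors <- (seq_along(event_probs) - 1) * stride_s
  timeline <- ifelse(!sleep_mask, "awake",
                     ifelse(event_probs >= event_threshold, "event", "normal"))
  is_ev <- timeline == "event"
  events <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (any(is_ev)) {
    r <- rle(is_ev)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ev <- which(r$values)
    events <- data.frame(start_s = anchors[starts[ev]],
                         end_s = anchors[ends[ev]] + window_s)
  }
  list(timeline = timeline, anchors = anchors, events = events)
}

#' Per-patient AHI report from window probabilities
#'
#' The estimator of the full pipeline, starting from per-window event and
#' sleep probabilities (so ground-truth labels can be substituted for
#' either model output): classify sleep, form the positive ratio over
#' sleep windows only, map it through the calibration regression, assign
#' the severity class, and build the night segmentation timeline.
#'
#' @param patient_id Identifier carried into the report.
#' @param event_probs,sleep_probs One probability per window (aligned).
#' @param calib A [calibration_model()].
#' @param stride_s,window_s Window geometry in seconds.
#' @return An `ahi_report` list; when no window is classified sleep the
#'   severity is "undetermined" and `no_sleep` is set.
#' @export
estimate_from_probs <- function(patient_id, event_probs, sleep_probs, calib,
                                stride_s = 15, window_s = 30) {
  stopifnot(length(event_probs) == length(sleep_probs))
  st <- estimate_sleep_time(sleep_probs, stride_s, calib$sleep_threshold)
  seg <- segment_night(event_probs, st$sleep_mask, calib$event_threshold,
                       stride_s, window_s)
  n_sleep <- sum(st$sleep_mask)
  if (n_sleep == 0) {
    rep <- list(patient_id = patient_id, total_sleep_h = 0,
                n_sleep_windows = 0L, n_positive_windows = 0L,
                positive_ratio = NA_real_, ahi_estimate = NA_real_,
                severity = "undetermined", no_sleep = TRUE,
                timeline = seg$timeline, anchors = seg$anchors,
                detected_events = seg$events)
    class(rep) <- "ahi_report"
    return(rep)
  }
  n_pos <- sum(seg$timeline == "event")
  ratio <- n_pos / n_sleep
  ahi <- predict_ahi(calib, ratio)
  rep <- list(patient_id = patient_id,
              total_sleep_h = st$total_sleep_h,
              n_sleep_windows = n_sleep,
              n_positive_windows = n_pos,
              positive_ratio = ratio,
              ahi_estimate = ahi,
              severity = severity_class(ahi),
              no_sleep = FALSE,
              timeline = seg$timeline,
              anchors = seg$anchors,
              detected_events = seg$events)
  class(rep) <- "ahi_report"
  rep
}

#' @export
print.ahi_report <- function(x, ...) {
  cat("AHI report for patient", x$patient_id, "\n")
  cat(sprintf("  estimated sleep time: %.2f h (%d windows)\n",
              x$total_sleep_h, x$n_sleep_windows))
  if (isTRUE(x$no_sleep)) {
    cat("  no sleep detected; AHI undetermined\n")
    return(invisible(x))
  }
  cat(sprintf("  positive windows: %d (ratio %.4f)\n",
              x$n_positive_windows, x$positive_ratio))
  cat(sprintf("  AHI estimate: %.2f events/h  [%s]\n",
              x$ahi_estimate, x$severity))
  cat(sprintf("  detected event intervals: %d\n", nrow(x$detected_events)))
  invisible(x)
}

#' Serialise an AHI report to JSON and the timeline to CSV
#'
#' @param report An `ahi_report`.
#' @param json_path,timeline_csv Output paths (either may be `NULL`).
#' @param event_probs Optional per-window probabilities echoed into the CSV.
#' @export
write_ahi_report <- function(report, json_path = NULL, timeline_csv = NULL,
                             event_probs = NULL) {
  if (!is.null(json_path)) {
    fields <- report[c("patient_id", "total_sleep_h", "n_sleep_windows",
                       "n_positive_windows", "positive_ratio",
                       "ahi_estimate", "severity")]
    jsonlite::write_json(fields, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(timeline_csv)) {
    df <- data.frame(step_start_s = report$anchors, state = report$timeline)
    if (!is.null(event_probs)) df$event_prob <- event_probs
    utils::write.csv(df, timeline_csv, row.names = FALSE)
  }
  invisible(report)
}
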