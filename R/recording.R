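# Core containers: multi-channel recording and scored-annotation set.

#' Construct a multi-channel recording
#'
#' @param patient_id Identifier string.
#' @param channels Named list; each element a list with `samples`
#'   (numeric vector), `rate` (Hz) and `physical_unit` (string).
#' @param duration_s Total duration in seconds; every channel must
#'   satisfy `length(samples) == round(rate * duration_s)`.
#' @param start_time Recording start, a `POSIXct`.
#' @return A `psg_recording` object.
#' @export
new_recording <- function(patient_id, channels, duration_s,
                          start_time = as.POSIXct("2000-01-01 22:00:00", tz = "UTC")) {
  assert_that(is.character(patient_id) && length(patient_id) == 1,
              "patient_id must be a single string")
  assert_that(duration_s >= 0, "duration_s must be non-negative")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    assert_that(ch$rate > 0, "channel ", nm, ": rate must be positive")
    n_expected <- round(ch$rate * duration_s)
    assert_that(length(ch$samples) == n_expected,
                "channel ", nm, ": has ", length(ch$samples),
                " samples, expected ", n_expected)
  }
  structure(list(patient_id = patient_id, channels = channels,
                 start_time = start_time, duration_s = duration_s),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("Recording %s: %.1f min, %d channel(s)\n",
              x$patient_id, x$duration_s / 60, length(x$channels)))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-10s %6g Hz  %8d samples [%s]\n",
                nm, ch$rate, length(ch$samples), ch$physical_unit))
  }
  invisible(x)
}

EVENT_TYPES <- c("apnea", "hypopnea", "hypopnea1", "hypopnea2", "hypopnea3",
                 "unsure", "noise")

empty_events <- function() {
  data.frame(type = character(0), start_s = numeric(0),
             duration_s = numeric(0), source_channel = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a scored-annotation set
#'
#' Holds scored respiratory events, arousals, desaturations and the 30 s
#' sleep-stage track, all in seconds from recording start with half-open
#' `[start, start + duration)` intervals.
#'
#' @param events data.frame with `type`, `start_s`, `duration_s` and
#'   optionally `source_channel`. Types are from the internal vocabulary
#'   (apnea, hypopnea, hypopnea1/2/3, unsure, noise); plain "hypopnea"
#'   marks a hypopnea whose subtype has not yet been derived.
#' @param arousals data.frame with `start_s`, `duration_s`.
#' @param desaturations data.frame with `start_s`, `duration_s`,
#'   `depth_percent`.
#' @param sleep_stages Character vector over `{"awake", "sleep"}`, one
#'   entry per 30 s epoch.
#' @param duration_s Recording duration the annotations refer to.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(events = empty_events(),
                           arousals = data.frame(start_s = numeric(0),
                                                 duration_s = numeric(0)),
                           desaturations = data.frame(start_s = numeric(0),
                                                      duration_s = numeric(0),
                                                      depth_percent = numeric(0)),
                           sleep_stages = character(0),
                           duration_s = NA_real_) {
  if (is.null(events$source_channel)) events$source_channel <- NA_character_
  events <- events[, c("type", "start_s", "duration_s", "source_channel")]
  assert_that(all(events$type %in% EVENT_TYPES),
              "unknown event type(s): ",
              paste(setdiff(events$type, EVENT_TYPES), collapse = ", "))
  assert_that(all(events$start_s >= 0) && all(events$duration_s >= 0),
              "event times must be non-negative")
  assert_that(all(sleep_stages %in% c("awake", "sleep")),
              "sleep_stages must be 'awake' or 'sleep'")
  if (!is.na(duration_s)) {
    ends <- c(events$start_s + events$duration_s,
              arousals$start_s + arousals$duration_s)
    assert_that(all(ends <= duration_s + 1e-9),
                "annotations extend past the recording end")
  }
  structure(list(events = events, arousals = arousals,
                 desaturations = desaturations,
                 sleep_stages = sleep_stages, duration_s = duration_s),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d event(s), %d arousal(s), %d desaturation(s), %d epoch(s)\n",
              nrow(x$events), nrow(x$arousals), nrow(x$desaturations),
              length(x$sleep_stages)))
  if (nrow(x$events)) print(table(x$events$type))
  invisible(x)
}
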