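# Fixed-length windowing, AASM-rule labels, and training-set balancing.

AHI_EVENT_TYPES <- c("apnea", "hypopnea1", "hypopnea2")

#' Classify a hypopnea into its AASM subtype
#'
#' Type 1 when a desaturation of at least 3% starts within 45 s of the
#' event onset; otherwise type 2 when an arousal starts within 5 s after
#' the event end (half-open `(end, end + 5]`); otherwise type 3, which
#' never counts toward the AHI. When both associations hold, the
#' desaturation rule takes precedence.
#'
#' @param event List or one-row data.frame with `start_s`, `duration_s`.
#' @param desaturations data.frame with `start_s`, `depth_percent`.
#' @param arousals data.frame with `start_s`.
#' @param desat_window_s,arousal_window_s Association windows (45 s from
#'   onset, 5 s after end).
#' @return One of `"hypopnea1"`, `"hypopnea2"`, `"hypopnea3"`.
#' @export
classify_hypopnea <- function(event, desaturations, arousals,
                              desat_window_s = 45, arousal_window_s = 5) {
  onset <- event$start_s
  end <- event$start_s + event$duration_s
  if (nrow(desaturations)) {
    hit <- desaturations$depth_percent >= 3 &
      desaturations$start_s >= onset &
      desaturations$start_s <= onset + desat_window_s
    if (any(hit)) return("hypopnea1")
  }
  if (nrow(arousals)) {
    hit <- arousals$start_s > end & arousals$start_s <= end + arousal_window_s
    if (any(hit)) return("hypopnea2")
  }
  "hypopnea3"
}

#' Resolve undated hypopnea subtypes in an annotation set
#'
#' Replaces every plain `"hypopnea"` event by the subtype derived with
#' [classify_hypopnea()] from the set's own desaturations and arousals
#' (used when the source file does not encode the subtype).
#'
#' @param annotations An [annotation_set()].
#' @export
derive_hypopnea_subtypes <- function(annotations) {
  ev <- annotations$events
  plain <- which(ev$type == "hypopnea")
  for (i in plain) {
    ev$type[i] <- classify_hypopnea(ev[i, ], annotations$desaturations,
                                    annotations$arousals)
  }
  annotations$events <- ev
  annotations
}

#' Segment a preprocessed recording into overlapping windows
#'
#' Anchors are laid at 0, `stride_s`, 2`stride_s`, ... and the last
#' window ends at or before the recording end:
#' `n = floor((duration - window_s) / stride_s) + 1`.
#'
#' @param preprocessed Output of [preprocess_recording()], or `NULL` to
#'   build an anchor-only dataset from `duration_s`.
#' @param window_s,stride_s Window length and stride in seconds.
#' @param duration_s Required when `preprocessed` is `NULL`.
#' @return A `window_dataset`: list with `windows` (array
#'   n x channels x samples, or `NULL`), `anchors`, `window_s`,
#'   `stride_s`, `rate`, `channel_names`, `patient_id`.
#' @export
make_windows <- function(preprocessed = NULL, window_s = 30, stride_s = 15,
                         duration_s = NULL) {
  if (!is.null(preprocessed)) duration_s <- preprocessed$duration_s
  assert_that(!is.null(duration_s) && duration_s >= window_s,
              "recording shorter than one window")
  n_windows <- floor((duration_s - window_s) / stride_s) + 1
  anchors <- (seq_len(n_windows) - 1) * stride_s
  windows <- NULL
  rate <- NULL
  channel_names <- NULL
  pid <- NULL
  if (!is.null(preprocessed)) {
    rate <- preprocessed$rate
    channel_names <- colnames(preprocessed$signals)
    pid <- preprocessed$patient_id
    wlen <- round(window_s * rate)
    nc <- ncol(preprocessed$signals)
    windows <- array(NA_real_, dim = c(n_windows, nc, wlen))
    for (w in seq_len(n_windows)) {
      i0 <- round(anchors[w] * rate)
      windows[w, , ] <- t(preprocessed$signals[(i0 + 1):(i0 + wlen), ,
                                               drop = FALSE])
    }
  }
  structure(list(windows = windows, anchors = anchors, window_s = window_s,
                 stride_s = stride_s, rate = rate,
                 channel_names = channel_names, patient_id = pid,
                 event_label = NULL, sleep_label = NULL),
            class = "window_dataset")
}

# Seconds of [a, b) lying in sleep-staged epochs.
sleep_overlap_s <- function(a, b, stages, epoch_s = 30) {
  if (!length(stages)) return(0)
  e0 <- max(0L, floor(a / epoch_s))
  e1 <- min(length(stages) - 1L, ceiling(b / epoch_s) - 1L)
  if (e1 < e0) return(0)
  total <- 0
  for (e in e0:e1) {
    if (stages[e + 1] == "sleep") {
      total <- total + interval_overlap(a, b, e * epoch_s, (e + 1) * epoch_s)
    }
  }
  total
}

#' Label windows with AHI-event and sleep states
#'
#' A window is event-positive when it overlaps an apnea, type-1 or
#' type-2 hypopnea by at least `overlap_s` seconds (type-3 hypopneas
#' never contribute), and sleep-labelled when at least half of it lies
#' in sleep-staged epochs. Labels depend only on the annotations, never
#' on channel content.
#'
#' @param dataset A `window_dataset` from [make_windows()].
#' @param annotations An [annotation_set()] on the same (trimmed) time
#'   base.
#' @param overlap_s Minimum event overlap that makes a window positive.
#' @return The dataset with `event_label` and `sleep_label` (0/1) filled.
#' @export
label_windows <- function(dataset, annotations, overlap_s = 1) {
  stopifnot(inherits(dataset, "window_dataset"))
  a <- dataset$anchors
  b <- a + dataset$window_s
  ev <- annotations$events
  ev <- ev[ev$type %in% AHI_EVENT_TYPES, , drop = FALSE]
  event_label <- integer(length(a))
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      ov <- interval_overlap(a, b, ev$start_s[k],
                             ev$start_s[k] + ev$duration_s[k])
      event_label[ov >= overlap_s] <- 1L
    }
  }
  sleep_label <- vapply(seq_along(a), function(w) {
    as.integer(sleep_overlap_s(a[w], b[w], annotations$sleep_stages) >=
                 dataset$window_s / 2)
  }, integer(1))
  dataset$event_label <- event_label
  dataset$sleep_label <- sleep_label
  dataset
}

#' Balance a labelled window set by downsampling negatives
#'
#' Keeps every event-positive window and draws an equal number of
#' negatives uniformly without replacement.
#'
#' @param dataset A labelled `window_dataset`.
#' @param seed RNG seed for the negative draw.
#' @return A `window_dataset` with equal label counts.
#' @export
balance_dataset <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "window_dataset"))
  assert_that(!is.null(dataset$event_label), "dataset must be labelled first")
  pos <- which(dataset$event_label == 1L)
  neg <- which(dataset$event_label == 0L)
  if (!length(pos)) stop_validation("nothing to balance: no positive windows")
  keep_neg <- if (length(neg) > length(pos)) {
    with_seed(seed, sort(sample(neg, length(pos))))
  } else neg
  subset_windows(dataset, sort(c(pos, keep_neg)))
}

#' Subset a window dataset by window index
#'
#' @param dataset A `window_dataset`.
#' @param idx Window indices to keep.
#' @export
subset_windows <- function(dataset, idx) {
  dataset$anchors <- dataset$anchors[idx]
  if (!is.null(dataset$windows)) {
    dataset$windows <- dataset$windows[idx, , , drop = FALSE]
  }
  for (f in c("event_label", "sleep_label")) {
    if (!is.null(dataset[[f]])) dataset[[f]] <- dataset[[f]][idx]
  }
  dataset
}

#' Merge consecutive positive windows into detected intervals
#'
#' Reassembles window-level labels over a night into half-open event
#' intervals `[first_anchor, last_anchor + window_s)`; used to check
#' labelling completeness against planted ground truth and as the
#' diagnostic event-count view of a night.
#'
#' @param anchors Window anchor times (s), constant stride.
#' @param labels 0/1 per window.
#' @param window_s Window length (s).
#' @export
merge_positive_windows <- function(anchors, labels, window_s = 30) {
  stopifnot(length(anchors) == length(labels))
  if (!any(labels == 1L)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  r <- rle(labels == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_s = anchors[starts[keep]],
             end_s = anchors[ends[keep]] + window_s)
}
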