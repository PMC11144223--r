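# Profusion-style XML annotation files: scored events with name / start /
# duration / input channel, and a sleep-stage code per 30 s epoch.

#' Default mapping from scored-event names to internal types
#'
#' Sleep-study cohorts use varying event vocabularies; this versioned
#' table maps
#' the common names (matched case-insensitively) onto the internal types.
#' "arousal" and "desaturation" route the event into the dedicated
#' arousal / desaturation tables rather than the respiratory event list.
#'
#' @return Named character vector: lower-case XML name -> internal type.
#' @export
default_event_map <- function() {
  c("obstructive apnea"    = "apnea",
    "central apnea"        = "apnea",
    "mixed apnea"          = "apnea",
    "apnea"                = "apnea",
    "hypopnea"             = "hypopnea",
    "obstructive hypopnea" = "hypopnea",
    "hypopnea type 1"      = "hypopnea1",
    "hypopnea type 2"      = "hypopnea2",
    "hypopnea type 3"      = "hypopnea3",
    "unsure"               = "unsure",
    "noise"                = "noise",
    "signal artifact"      = "noise",
    "arousal"              = "arousal",
    "arousal ()"           = "arousal",
    "spo2 desaturation"    = "desaturation",
    "desaturation"         = "desaturation")
}

# Internal type -> canonical name written to XML.
write_names <- c(apnea = "Obstructive Apnea", hypopnea = "Hypopnea",
                 hypopnea1 = "Hypopnea Type 1", hypopnea2 = "Hypopnea Type 2",
                 hypopnea3 = "Hypopnea Type 3", unsure = "Unsure",
                 noise = "Noise")

#' Read a profusion-style XML annotation file
#'
#' Scored events are mapped to the internal type vocabulary through
#' `event_map`; arousals and desaturations are routed into their own
#' tables; sleep-stage codes are collapsed to a binary awake/sleep track
#' (code 0 = awake, every other stage = sleep).
#'
#' @param path XML file path.
#' @param event_map Name mapping, see [default_event_map()].
#' @param strict If `TRUE`, an unmapped event name is an error; otherwise
#'   it becomes type "unsure" with a warning.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, event_map = default_event_map(),
                             strict = FALSE) {
  doc <- xml2::read_xml(path)
  ev_nodes <- xml2::xml_find_all(doc, ".//ScoredEvent")
  events <- empty_events()
  arousals <- data.frame(start_s = numeric(0), duration_s = numeric(0))
  desats <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                       depth_percent = numeric(0))
  for (node in ev_nodes) {
    name <- xml2::xml_text(xml2::xml_find_first(node, "./Name"))
    start <- as.numeric(xml2::xml_text(xml2::xml_find_first(node, "./Start")))
    dur <- as.numeric(xml2::xml_text(xml2::xml_find_first(node, "./Duration")))
    input <- xml2::xml_text(xml2::xml_find_first(node, "./Input"))
    type <- unname(event_map[tolower(name)])
    if (is.na(type)) {
      if (strict) stop("unmapped scored-event name: ", name)
      warning("unmapped scored-event name '", name, "' recorded as 'unsure'")
      type <- "unsure"
    }
    if (type == "arousal") {
      arousals <- rbind(arousals, data.frame(start_s = start, duration_s = dur))
    } else if (type == "desaturation") {
      depth_node <- xml2::xml_find_first(node, "./Desaturation")
      depth <- as.numeric(xml2::xml_text(depth_node))
      desats <- rbind(desats, data.frame(start_s = start, duration_s = dur,
                                         depth_percent = depth))
    } else {
      events <- rbind(events, data.frame(type = type, start_s = start,
                                         duration_s = dur,
                                         source_channel = input,
                                         stringsAsFactors = FALSE))
    }
  }
  stage_nodes <- xml2::xml_find_all(doc, ".//SleepStages/SleepStage")
  codes <- as.integer(xml2::xml_text(stage_nodes))
  stages <- ifelse(codes == 0L, "awake", "sleep")
  annotation_set(events = events, arousals = arousals, desaturations = desats,
                 sleep_stages = stages)
}

#' Write an annotation set to a profusion-style XML file
#'
#' Inverse of [read_annotations()]: internal types are written under
#' their canonical names, desaturation depth goes into a
#' `<Desaturation>` child, and the binary stage track is written as
#' codes 0 (awake) / 2 (sleep).
#'
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  doc <- xml2::xml_new_root("CMPStudyConfig")
  xml2::xml_add_child(doc, "EpochLength", "30")
  scored <- xml2::xml_add_child(doc, "ScoredEvents")
  add_event <- function(name, start, dur, input = NULL, depth = NULL) {
    node <- xml2::xml_add_child(scored, "ScoredEvent")
    xml2::xml_add_child(node, "Name", name)
    xml2::xml_add_child(node, "Start", format(start, digits = 12))
    xml2::xml_add_child(node, "Duration", format(dur, digits = 12))
    if (!is.null(input) && !is.na(input)) xml2::xml_add_child(node, "Input", input)
    if (!is.null(depth)) xml2::xml_add_child(node, "Desaturation",
                                             format(depth, digits = 12))
  }
  ev <- annotations$events
  for (i in seq_len(nrow(ev))) {
    add_event(write_names[[ev$type[i]]], ev$start_s[i], ev$duration_s[i],
              ev$source_channel[i])
  }
  ar <- annotations$arousals
  for (i in seq_len(nrow(ar))) {
    add_event("Arousal", ar$start_s[i], ar$duration_s[i])
  }
  de <- annotations$desaturations
  for (i in seq_len(nrow(de))) {
    add_event("SpO2 desaturation", de$start_s[i], de$duration_s[i],
              depth = de$depth_percent[i])
  }
  stages <- xml2::xml_add_child(doc, "SleepStages")
  for (s in annotations$sleep_stages) {
    xml2::xml_add_child(stages, "SleepStage", if (s == "awake") "0" else "2")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Apply the recording-level exclusion criteria
#'
#' A recording is excluded when (a) the summed duration of "unsure" or
#' "noise" scored events exceeds one third of the total sleep time
#' (strictly greater), (b) any required channel is constant over the
#' whole recording, or (c) any required channel is missing. Zero
#' annotated sleep excludes the recording outright.
#'
#' @param recording A `psg_recording`.
#' @param annotations An [annotation_set()] aligned to it.
#' @param required_channels Channels that must be present and
#'   non-constant.
#' @return List with `keep` (flag) and `reasons` (character).
#' @export
exclude_recording <- function(recording, annotations,
                              required_channels = c("abdominal", "thoracic", "spo2")) {
  reasons <- character(0)
  missing <- setdiff(required_channels, names(recording$channels))
  if (length(missing)) {
    reasons <- c(reasons, paste0("missing channel: ", missing))
  }
  for (nm in intersect(required_channels, names(recording$channels))) {
    s <- recording$channels[[nm]]$samples
    if (length(s) && length(unique(s)) == 1L) {
      reasons <- c(reasons, paste0("constant channel: ", nm))
    }
  }
  sleep_s <- sum(annotations$sleep_stages == "sleep") * 30
  if (sleep_s <= 0) {
    reasons <- c(reasons, "no sleep")
  } else {
    bad <- annotations$events$type %in% c("unsure", "noise")
    bad_s <- sum(annotations$events$duration_s[bad])
    if (bad_s > sleep_s / 3) {
      reasons <- c(reasons,
                   sprintf("unsure/noise time %.0f s exceeds a third of sleep time %.0f s",
                           bad_s, sleep_s))
    }
  }
  list(keep = length(reasons) == 0L, reasons = reasons)
}
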