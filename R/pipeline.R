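# End-to-end orchestration: leakage-safe patient splits, per-channel
# extractor + stacker training, threshold and AHI-regression calibration,
# and whole-night estimation.

#' Split patients into partitions without leakage
#'
#' Grouping is by patient: repeat recordings of one patient always land
#' in the same partition. Partition sizes match the requested fractions
#' to within one patient.
#'
#' @param patient_ids Character vector, one entry per recording (repeats
#'   mark repeat recordings of the same patient).
#' @param fractions Named fractions summing to 1, e.g.
#'   `c(train = .8, val = .2)`.
#' @param seed Shuffle seed.
#' @return List with `assignment` (partition per input recording) and
#'   `patients` (named list of unique patient ids per partition).
#' @export
split_patients <- function(patient_ids, fractions = c(train = 0.8, val = 0.2),
                           seed = 1L) {
  assert_that(abs(sum(fractions) - 1) < 1e-8, "fractions must sum to 1")
  uniq <- unique(patient_ids)
  if (length(uniq) < length(fractions)) {
    stop_validation("fewer patients (", length(uniq),
                    ") than partitions (", length(fractions), ")")
  }
  shuffled <- with_seed(seed, sample(uniq))
  bounds <- round(cumsum(fractions) * length(uniq))
  counts <- diff(c(0, bounds))
  part_of <- rep(names(fractions), times = counts)
  names(part_of) <- shuffled
  assignment <- unname(part_of[patient_ids])
  patients <- split(shuffled, factor(part_of[shuffled], levels = names(fractions)))
  # leakage assertion: every patient maps to exactly one partition
  stopifnot(!anyDuplicated(unlist(patients)))
  list(assignment = assignment, patients = patients)
}

# Windows + labels for one simulated patient on the trimmed time base.
patient_windows <- function(entry, channels, pcfg, window_s = 30,
                            stride_s = 15, materialize = TRUE) {
  pp <- preprocess_recording(entry$recording, channels = channels,
                             config = pcfg)
  ann <- trim_annotations(entry$annotations, pcfg$trim_min,
                          entry$recording$duration_s)
  wd <- make_windows(if (materialize) pp else NULL, window_s, stride_s,
                     duration_s = pp$duration_s)
  wd$patient_id <- entry$recording$patient_id
  if (is.null(wd$channel_names)) wd$channel_names <- colnames(pp$signals)
  label_windows(wd, ann)
}

balance_indices <- function(labels, seed) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (!length(pos) || !length(neg)) return(seq_along(labels))
  n <- min(length(pos), length(neg))
  sort(c(
    if (length(pos) > n) with_seed(derive_seed(seed, 1L), sample(pos, n)) else pos,
    if (length(neg) > n) with_seed(derive_seed(seed, 2L), sample(neg, n)) else neg
  ))
}

# Concatenated per-channel features in the stable channel order of the
# extractor list.
stacked_features <- function(extractors, windows, channel_names,
                             feature_layer = "last_gap") {
  mats <- lapply(names(extractors), function(ch) {
    ci <- match(ch, channel_names)
    if (is.na(ci)) stop_validation("channel order mismatch: ", ch,
                                   " absent from window channels")
    X <- windows[, ci, , drop = FALSE]
    dim(X) <- dim(X)[c(1, 3)]
    extract_features(extractors[[ch]], X, feature_layer)
  })
  do.call(cbind, mats)
}

train_task_models <- function(pool, channels, extractor_cfg,
                              stacker_budget, seed) {
  y_tr <- pool$train_labels
  y_va <- pool$val_labels
  extractors <- list()
  for (ch in channels) {
    ci <- match(ch, pool$channel_names)
    Xtr <- pool$train_windows[, ci, , drop = FALSE]
    dim(Xtr) <- dim(Xtr)[c(1, 3)]
    Xva <- pool$val_windows[, ci, , drop = FALSE]
    dim(Xva) <- dim(Xva)[c(1, 3)]
    cfg <- extractor_cfg
    cfg$seed <- derive_seed(seed, match(ch, channels))
    model <- build_extractor(cfg)
    extractors[[ch]] <- train_extractor(model, Xtr, y_tr, Xva, y_va)
  }
  ftr <- stacked_features(extractors, pool$train_windows,
                          pool$channel_names, extractor_cfg$feature_layer)
  fva <- stacked_features(extractors, pool$val_windows,
                          pool$channel_names, extractor_cfg$feature_layer)
  stacker <- fit_stacker(ftr, y_tr, fva, y_va,
                         search_budget = stacker_budget,
                         seed = derive_seed(seed, 53L))
  list(extractors = extractors, stacker = stacker)
}

#' Train the full pipeline on a cohort and evaluate it
#'
#' Splits the training cohort by patient into train/validation, trains a
#' per-channel extractor and stacker for the AHI-event task and (with
#' the identical architecture, switched to the sleep label) for the
#' sleep/awake task, selects the event threshold where precision equals
#' recall on validation windows, fits the positive-ratio to AHI
#' regression on the validation patients, and evaluates on the held-out
#' test cohort.
#'
#' @param train_cohort,test_cohort Lists of patients from
#'   [simulate_cohort()] (or equivalent recording/annotations/truth
#'   triples with a `target_ahi`).
#' @param channels Input channels, in the (stable) order features are
#'   concatenated.
#' @param extractor_cfg An [extractor_config()].
#' @param pcfg A [preprocess_config()].
#' @param stacker_budget Random-search budget for the stacker.
#' @param windows_per_patient Cap on balanced training windows drawn per
#'   patient.
#' @param val_fraction Fraction of training patients held out for
#'   validation/calibration.
#' @param seed Master seed for splitting, balancing and training.
#' @return List with the trained models, the [calibration_model()],
#'   per-test-patient `reports`, and window/patient-level `metrics`.
#' @export
run_pipeline <- function(train_cohort, test_cohort,
                         channels = c("abdominal", "spo2"),
                         extractor_cfg = extractor_config("tiny"),
                         pcfg = preprocess_config(trim_min = 0,
                                                  spo2_delays = numeric(0)),
                         stacker_budget = 6L,
                         windows_per_patient = 80L,
                         val_fraction = 0.25,
                         seed = 1L) {
  ids <- vapply(train_cohort, function(e) e$recording$patient_id, "")
  sp <- split_patients(ids, c(train = 1 - val_fraction, val = val_fraction),
                       seed = derive_seed(seed, 3L))

  # pool windows per patient, balanced separately for each task
  acc <- list(
    event = list(train_w = list(), train_y = list(),
                 val_w = list(), val_y = list()),
    sleep = list(train_w = list(), train_y = list(),
                 val_w = list(), val_y = list())
  )
  val_entries <- list()
  channel_names <- NULL
  for (i in seq_along(train_cohort)) {
    entry <- train_cohort[[i]]
    wd <- patient_windows(entry, channels, pcfg)
    channel_names <- wd$channel_names
    part <- if (sp$assignment[i] == "train") "train" else "val"
    if (part == "val") val_entries[[length(val_entries) + 1L]] <- entry
    for (task in c("event", "sleep")) {
      lab <- if (task == "event") wd$event_label else wd$sleep_label
      bal <- balance_indices(lab, derive_seed(seed, 100L + 2L * i +
                                                (task == "sleep")))
      if (length(bal) > windows_per_patient) {
        bal <- with_seed(derive_seed(seed, 300L + 2L * i + (task == "sleep")),
                         sort(sample(bal, windows_per_patient)))
      }
      acc[[task]][[paste0(part, "_w")]] <-
        c(acc[[task]][[paste0(part, "_w")]], list(wd$windows[bal, , , drop = FALSE]))
      acc[[task]][[paste0(part, "_y")]] <-
        c(acc[[task]][[paste0(part, "_y")]], list(lab[bal]))
    }
  }
  bind_w <- function(lst) {
    out <- array(0, c(sum(vapply(lst, function(w) dim(w)[1], 0L)),
                      dim(lst[[1]])[2], dim(lst[[1]])[3]))
    at <- 0L
    for (w in lst) {
      out[at + seq_len(dim(w)[1]), , ] <- w
      at <- at + dim(w)[1]
    }
    out
  }
  task_pool <- function(task) {
    list(train_windows = bind_w(acc[[task]]$train_w),
         val_windows = bind_w(acc[[task]]$val_w),
         train_labels = unlist(acc[[task]]$train_y),
         val_labels = unlist(acc[[task]]$val_y),
         channel_names = channel_names)
  }

  event_models <- train_task_models(task_pool("event"), channels, extractor_cfg,
                                    stacker_budget, derive_seed(seed, 11L))
  sleep_models <- train_task_models(task_pool("sleep"), channels, extractor_cfg,
                                    stacker_budget, derive_seed(seed, 13L))

  # per-patient probabilities over the full night
  night_probs <- function(entry) {
    wd <- patient_windows(entry, channels, pcfg)
    f_ev <- stacked_features(event_models$extractors, wd$windows,
                             wd$channel_names, extractor_cfg$feature_layer)
    f_sl <- stacked_features(sleep_models$extractors, wd$windows,
                             wd$channel_names, extractor_cfg$feature_layer)
    list(event = predict_proba(event_models$stacker, f_ev),
         sleep = predict_proba(sleep_models$stacker, f_sl),
         event_label = wd$event_label, sleep_label = wd$sleep_label,
         patient_id = wd$patient_id)
  }

  val_probs <- lapply(val_entries, night_probs)
  threshold <- select_threshold(unlist(lapply(val_probs, `[[`, "event")),
                                unlist(lapply(val_probs, `[[`, "event_label")))

  ratios <- vapply(val_probs, function(p) {
    mask <- p$sleep >= 0.5
    if (!any(mask)) return(NA_real_)
    sum(p$event >= threshold & mask) / sum(mask)
  }, numeric(1))
  true_ahis <- vapply(val_entries, function(e) e$truth$planted_ahi, numeric(1))
  if (isTRUE(getOption("driven.debug"))) {
    message("event threshold: ", round(threshold, 4))
    message("val ratios: ", paste(round(ratios, 4), collapse = " "),
            " | true AHI: ", paste(round(true_ahis, 1), collapse = " "))
  }
  ok <- !is.na(ratios)
  reg <- fit_ahi_regression(ratios[ok], true_ahis[ok])
  calib <- calibration_model(threshold, reg$slope, reg$intercept)

  test_probs <- lapply(test_cohort, night_probs)
  reports <- lapply(test_probs, function(p) {
    estimate_from_probs(p$patient_id, p$event, p$sleep, calib)
  })
  true_test_ahi <- vapply(test_cohort, function(e) e$truth$planted_ahi, numeric(1))
  pred_class <- vapply(reports, `[[`, "", "severity")
  true_class <- severity_class(true_test_ahi)
  auroc <- roc_auc(unlist(lapply(test_probs, `[[`, "event")),
                   unlist(lapply(test_probs, `[[`, "event_label")))
  auprc <- pr_auc(unlist(lapply(test_probs, `[[`, "event")),
                  unlist(lapply(test_probs, `[[`, "event_label")))
  sleep_auroc <- roc_auc(unlist(lapply(test_probs, `[[`, "sleep")),
                         unlist(lapply(test_probs, `[[`, "sleep_label")))
  ahi_metrics <- f1_ahi(true_class, pred_class)

  list(event_models = event_models, sleep_models = sleep_models,
       calib = calib, reports = reports,
       metrics = list(window_auroc = auroc, window_auprc = auprc,
                      sleep_auroc = sleep_auroc,
                      severity = ahi_metrics,
                      true_ahi = true_test_ahi,
                      est_ahi = vapply(reports, `[[`, 0, "ahi_estimate")))
}

#' Estimate one patient's AHI with trained models
#'
#' Runs preprocessing, windowing, feature extraction, the two stackers
#' and the calibrated estimator on a single recording.
#'
#' @param recording A `psg_recording`.
#' @param event_models,sleep_models Model bundles from [run_pipeline()]
#'   (`extractors` + `stacker`).
#' @param calib A [calibration_model()].
#' @param channels Channels in the training order.
#' @param pcfg The [preprocess_config()] used at training time.
#' @param feature_layer Feature layer used at training time.
#' @return An `ahi_report`.
#' @export
estimate_patient <- function(recording, event_models, sleep_models, calib,
                             channels = c("abdominal", "spo2"),
                             pcfg = preprocess_config(trim_min = 0,
                                                      spo2_delays = numeric(0)),
                             feature_layer = "last_gap") {
  pp <- preprocess_recording(recording, channels = channels, config = pcfg)
  wd <- make_windows(pp)
  f_ev <- stacked_features(event_models$extractors, wd$windows,
                           wd$channel_names, feature_layer)
  f_sl <- stacked_features(sleep_models$extractors, wd$windows,
                           wd$channel_names, feature_layer)
  estimate_from_probs(recording$patient_id,
                      predict_proba(event_models$stacker, f_ev),
                      predict_proba(sleep_models$stacker, f_sl),
                      calib)
}
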