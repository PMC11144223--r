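# European Data Format (EDF) reader and writer, 16-bit samples.
# Written from the published format description: a 256-byte fixed header,
# 256 bytes per signal of per-signal header fields, then data records of
# little-endian int16 samples scaled by the physical/digital linear map.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d, width = -1)
    if (nchar(s) <= width) return(edf_pad(s, width))
  }
  edf_pad(sprintf("%.1e", x), width)
}

#' Write a recording to an EDF file
#'
#' Standard EDF with 1 s data records and 16-bit samples. The physical
#' min/max of each signal is taken from a `phys_range` element on the
#' channel when present (as set by [read_edf()]), otherwise from the data
#' range, so a read-write cycle reproduces the signal payload exactly.
#'
#' @param recording A `psg_recording`; all sampling rates must be whole
#'   numbers (samples per 1 s record) and the duration a whole number of
#'   seconds.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "psg_recording"))
  channels <- recording$channels
  if (length(channels) == 0) stop_validation("recording has no channels")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (any(!is.finite(ch$samples))) {
      stop_validation("channel ", nm, " contains non-finite samples")
    }
    if (abs(ch$rate - round(ch$rate)) > 1e-9) {
      stop_validation("channel ", nm, ": rate must be an integer (1 s records)")
    }
  }
  n_records <- round(recording$duration_s)
  if (abs(recording$duration_s - n_records) > 1e-9) {
    stop_validation("duration must be a whole number of seconds for 1 s records")
  }
  ns <- length(channels)

  ranges <- lapply(channels, function(ch) {
    pr <- ch$phys_range
    if (is.null(pr)) {
      pr <- range(ch$samples)
      if (diff(pr) == 0) pr <- pr + c(-1, 1)
    }
    # scale with the value as written to the 8-char ASCII field, so the
    # reader's linear map is exactly the writer's; widen until the
    # formatted bounds actually enclose the data
    lo <- min(ch$samples); hi <- max(ch$samples)
    eps_lo <- 1e-11 * max(1, abs(lo))  # 1-ulp slack: clamping absorbs it
    eps_hi <- 1e-11 * max(1, abs(hi))
    v <- pr[1]; step <- max(1e-12, abs(lo) * 1e-7)
    repeat {
      p <- as.numeric(edf_num(v))
      if (p <= lo + eps_lo) break
      v <- v - step; step <- step * 10
    }
    pr[1] <- p
    v <- pr[2]; step <- max(1e-12, abs(hi) * 1e-7)
    repeat {
      p <- as.numeric(edf_num(v))
      if (p >= hi - eps_hi) break
      v <- v + step; step <- step * 10
    }
    pr[2] <- p
    pr
  })

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  st <- recording$start_time
  wr(edf_pad("0", 8))
  wr(edf_pad(recording$patient_id, 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad(format(st, "%d.%m.%y"), 8))
  wr(edf_pad(format(st, "%H.%M.%S"), 8))
  wr(edf_pad(256 * (ns + 1), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_records, 8))
  wr(edf_pad("1", 8))
  wr(edf_pad(ns, 4))
  wr(paste0(vapply(names(channels), edf_pad, "", width = 16), collapse = ""))
  wr(strrep(" ", 80 * ns))
  wr(paste0(vapply(channels, function(ch)
    edf_pad(ch$physical_unit %||% "", 8), ""), collapse = ""))
  wr(paste0(vapply(ranges, function(r) edf_num(r[1]), ""), collapse = ""))
  wr(paste0(vapply(ranges, function(r) edf_num(r[2]), ""), collapse = ""))
  wr(paste0(rep(edf_pad("-32768", 8), ns), collapse = ""))
  wr(paste0(rep(edf_pad("32767", 8), ns), collapse = ""))
  wr(strrep(" ", 80 * ns))
  wr(paste0(vapply(channels, function(ch)
    edf_pad(round(ch$rate), 8), ""), collapse = ""))
  wr(strrep(" ", 32 * ns))

  # digital conversion once per channel, then interleave by record
  digital <- vector("list", ns)
  spr <- integer(ns)
  for (i in seq_len(ns)) {
    ch <- channels[[i]]
    r <- ranges[[i]]
    scale <- 65535 / (r[2] - r[1])
    d <- round((ch$samples - r[1]) * scale) - 32768
    digital[[i]] <- as.integer(pmin(32767, pmax(-32768, d)))
    spr[i] <- round(ch$rate)
  }
  for (rec in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      idx <- ((rec - 1) * spr[i] + 1):(rec * spr[i])
      writeBin(digital[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_ascii <- function(con, n) {
  trimws(readChar(con, n, useBytes = TRUE))
}

#' Read an EDF file into a recording
#'
#' Sampling rates are computed from the header (samples per record /
#' record duration) and digital values are mapped to physical units via
#' the header's physical/digital linear map. The original physical range
#' is kept on each channel as `phys_range` so that [write_edf()] can
#' reproduce the byte payload.
#'
#' @param path EDF file path.
#' @return A `psg_recording`.
#' @export
read_edf <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 256) stop("not an EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (version != "0") stop("not an EDF file (bad version field): ", path)
  patient_id <- read_ascii(con, 80)
  read_ascii(con, 80)                      # recording id
  date_s <- read_ascii(con, 8)
  time_s <- read_ascii(con, 8)
  header_bytes <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("EDF header: invalid signal count")
  if (is.na(n_records) || n_records < 0) {
    stop("EDF header: unknown record count (-1) is not supported")
  }

  fields <- function(width) {
    vapply(seq_len(ns), function(i) read_ascii(con, width), "")
  }
  labels <- fields(16)
  fields(80)                               # transducer
  units <- fields(8)
  pmin <- as.numeric(fields(8))
  pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8))
  dmax <- as.numeric(fields(8))
  fields(80)                               # prefiltering
  spr <- as.integer(fields(8))
  fields(32)                               # reserved

  record_bytes <- sum(spr) * 2
  available <- size - header_bytes
  complete <- available %/% record_bytes
  if (complete < n_records) {
    stop(sprintf("EDF data truncated: record %d of %d is incomplete or missing",
                 complete + 1, n_records))
  }

  raw_all <- readBin(con, integer(), n = sum(spr) * n_records, size = 2,
                     signed = TRUE, endian = "little")
  # de-interleave records
  channels <- stats::setNames(vector("list", ns), labels)
  offsets <- c(0, cumsum(spr))
  per_record <- sum(spr)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(offsets[i] + seq_len(spr[i]),
                           (seq_len(n_records) - 1) * per_record, "+"))
    dig <- raw_all[idx]
    phys <- (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
    channels[[i]] <- list(samples = phys, rate = spr[i] / record_dur,
                          physical_unit = units[i],
                          phys_range = c(pmin[i], pmax[i]))
  }
  start_time <- as.POSIXct(paste(date_s, time_s), format = "%d.%m.%y %H.%M.%S",
                           tz = "UTC")
  if (is.na(start_time)) start_time <- as.POSIXct("2000-01-01", tz = "UTC")
  new_recording(patient_id, channels, n_records * record_dur,
                start_time = start_time)
}
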