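# On-disk data model: a session is a directory holding channels.tsv,
# events.tsv, signal.bin (little-endian float32, channel-major) and a
# signal.json sidecar (fs, channel order, units). Result tables are TSV
# with a JSON run manifest.

#' Construct and validate a recording
#'
#' @param participant_id Participant identifier.
#' @param fs Sampling rate in Hz (>= 1000).
#' @param channels Data frame of channel metadata with columns `site_id`,
#'   `roi`, `hemisphere`, `clinically_excluded` (and optionally
#'   `mni_x/mni_y/mni_z`).
#' @param voltage Channels x samples numeric matrix (microvolts).
#' @param line_freq Power-line frequency in Hz.
#' @return Object of class `hfb_recording`.
#' @export
hfb_recording <- function(participant_id, fs, channels, voltage,
                          line_freq = 60) {
  rec <- structure(list(participant_id = participant_id, fs = fs,
                        channels = channels, voltage = voltage,
                        line_freq = line_freq),
                   class = "hfb_recording")
  validate_recording(rec)
  rec
}

#' @export
print.hfb_recording <- function(x, ...) {
  cat(sprintf("<hfb_recording> participant %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, nrow(x$voltage), ncol(x$voltage), x$fs,
              ncol(x$voltage) / x$fs))
  invisible(x)
}

#' Validate a recording object
#'
#' Checks the container invariants: sampling rate >= 1000 Hz, voltage row
#' count equals channel count, no NaN/NA voltage, unique site ids.
#'
#' @param rec An `hfb_recording`.
#' @return Invisibly `rec`; errors name the offending field.
#' @export
validate_recording <- function(rec) {
  ch <- rec$channels
  need <- c("site_id", "roi", "hemisphere", "clinically_excluded")
  miss <- setdiff(need, names(ch))
  if (length(miss)) stopf("recording$channels: missing column(s) %s",
                          paste(miss, collapse = ", "))
  if (!is.numeric(rec$fs) || rec$fs < 1000)
    stopf("recording$fs: sampling rate must be >= 1000 Hz (got %s)", rec$fs)
  if (!is.matrix(rec$voltage))
    stopf("recording$voltage: must be a channels x samples matrix")
  if (nrow(rec$voltage) != nrow(ch))
    stopf("recording$voltage: %d rows but %d channels",
          nrow(rec$voltage), nrow(ch))
  if (anyNA(rec$voltage))
    stopf("recording$voltage: contains NA/NaN")
  if (anyDuplicated(ch$site_id))
    stopf("recording$channels$site_id: duplicated site ids")
  bad <- setdiff(unique(as.character(ch$roi)), roi_levels())
  if (length(bad)) stopf("recording$channels$roi: unknown ROI label(s) %s",
                         paste(bad, collapse = ", "))
  invisible(rec)
}

#' Validate an event table
#'
#' Enforces the event-table invariants: strictly increasing stimulus
#' onsets, responses after onsets, `rt_ms` consistent with the sample
#' indices at the recording's sampling rate.
#'
#' @param events Data frame with columns `trial_id`, `condition`,
#'   `stim_onset`, `response_sample`, `rt_ms`, `choice`, `trait`,
#'   `trait_valence`, `vd1`, `vd2`, `hfo_flag`, `irrelevant_press`.
#' @param fs Sampling rate used to check `rt_ms`.
#' @return Invisibly `events`.
#' @export
validate_events <- function(events, fs = 1000) {
  need <- c("trial_id", "condition", "stim_onset", "response_sample",
            "rt_ms", "choice", "trait_valence", "vd1", "vd2",
            "hfo_flag", "irrelevant_press")
  miss <- setdiff(need, names(events))
  if (length(miss)) stopf("events: missing column(s) %s",
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(as.character(events$condition)), condition_levels())
  if (length(bad)) stopf("events$condition: unknown condition(s) %s",
                         paste(bad, collapse = ", "))
  if (is.unsorted(events$stim_onset, strictly = TRUE))
    stopf("events$stim_onset: must be strictly increasing")
  has_resp <- !is.na(events$response_sample)
  if (any(events$response_sample[has_resp] <= events$stim_onset[has_resp]))
    stopf("events$response_sample: must exceed stim_onset when present")
  rt_chk <- (events$response_sample[has_resp] -
               events$stim_onset[has_resp]) / fs * 1000
  if (any(abs(events$rt_ms[has_resp] - rt_chk) > 0.51))
    stopf("events$rt_ms: inconsistent with (response_sample - stim_onset)/fs")
  invisible(events)
}

#' Write a session directory
#'
#' Writes `channels.tsv`, `events.tsv`, `signal.bin` (little-endian
#' float32, channel-major) and `signal.json` into `path`.
#'
#' @param rec An `hfb_recording`.
#' @param events An event table.
#' @param path Output directory (created if needed).
#' @return Invisibly `path`.
#' @export
write_session <- function(rec, events, path) {
  validate_recording(rec)
  validate_events(events, rec$fs)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.table(rec$channels, file.path(path, "channels.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(events, file.path(path, "events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  con <- file(file.path(path, "signal.bin"), "wb")
  on.exit(close(con))
  # channel-major: one channel's full timecourse after another
  writeBin(as.numeric(t(rec$voltage)), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(participant_id = rec$participant_id, fs = rec$fs,
         line_freq = rec$line_freq, n_channels = nrow(rec$voltage),
         n_samples = ncol(rec$voltage), dtype = "float32le",
         order = "channel_major", units = "uV",
         channel_names = as.character(rec$channels$site_id)),
    file.path(path, "signal.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session directory
#'
#' Loads and validates the recording and event table written by
#' [write_session()].
#'
#' @param path Session directory.
#' @return List with elements `recording` and `events`.
#' @export
read_session <- function(path) {
  for (f in c("channels.tsv", "events.tsv", "signal.bin", "signal.json"))
    if (!file.exists(file.path(path, f)))
      stopf("read_session: missing file '%s' in %s", f, path)
  meta <- jsonlite::read_json(file.path(path, "signal.json"),
                              simplifyVector = TRUE)
  channels <- read.delim(file.path(path, "channels.tsv"),
                         stringsAsFactors = FALSE)
  channels$clinically_excluded <- as.logical(channels$clinically_excluded)
  events <- read.delim(file.path(path, "events.tsv"),
                       stringsAsFactors = FALSE)
  for (cc in c("hfo_flag", "irrelevant_press"))
    events[[cc]] <- as.logical(events[[cc]])
  n <- meta$n_channels * meta$n_samples
  con <- file(file.path(path, "signal.bin"), "rb")
  v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  close(con)
  if (length(v) != n)
    stopf("read_session: signal.bin has %d values, expected %d", length(v), n)
  voltage <- t(matrix(v, nrow = meta$n_samples, ncol = meta$n_channels))
  rec <- hfb_recording(meta$participant_id, meta$fs, channels, voltage,
                       meta$line_freq)
  validate_events(events, rec$fs)
  list(recording = rec, events = events)
}

#' Write result tables with a run manifest
#'
#' Each table is written as TSV with a typed header line (`#types:` comment
#' giving the column classes); a `manifest.json` captures the configuration
#' hash, seed and package version so any table can be reproduced.
#'
#' @param tables Named list of data frames.
#' @param path Output directory.
#' @param config Configuration list recorded (hashed) in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Invisibly the manifest list.
#' @export
write_results <- function(tables, path, config = list(), seed = NA) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".tsv"))
    tab <- tables[[nm]]
    con <- file(f, "w")
    writeLines(paste0("#types:", paste(vapply(tab, function(col)
      class(col)[1], ""), collapse = "\t")), con)
    close(con)
    suppressWarnings(write.table(tab, f, sep = "\t", row.names = FALSE,
                                 quote = FALSE, append = TRUE))
  }
  manifest <- list(
    config_hash = config_hash(config), seed = seed,
    package = "hfbseq",
    version = as.character(packageVersion("hfbseq")),
    tables = as.list(names(tables)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a result table written by [write_results()]
#'
#' @param file Path to the TSV file.
#' @return Data frame with column classes restored from the typed header.
#' @export
read_results_table <- function(file) {
  hdr <- readLines(file, n = 1)
  types <- NULL
  if (startsWith(hdr, "#types:"))
    types <- strsplit(sub("^#types:", "", hdr), "\t")[[1]]
  tab <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(types) && length(types) == ncol(tab)) {
    for (j in seq_along(types)) {
      tab[[j]] <- switch(types[j],
                         logical = as.logical(tab[[j]]),
                         integer = as.integer(tab[[j]]),
                         numeric = as.numeric(tab[[j]]),
                         tab[[j]])
    }
  }
  tab
}
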