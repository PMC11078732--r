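#' Epoch a continuous trace around trial events
#'
#' Cuts a continuous single-channel recording into a trials x time matrix
#' aligned to per-trial event times. The sample at trial-relative time 0 is the
#' sample whose timestamp is closest-from-below to the event; windows are
#' half-open `[window[1], window[2])` so a 3.5 s window at 400 Hz always yields
#' 1400 samples. Trials whose window extends beyond the recording are flagged
#' invalid (all-NA row), not dropped, so trial indices stay aligned with the
#' trial table.
#'
#' @param trace numeric vector, continuous recording in microvolts.
#' @param fs sampling rate of `trace` in Hz.
#' @param events numeric vector of event times (seconds, session clock),
#'   typically `trialInfo(session)$maintenance_onset`.
#' @param window length-2 numeric, seconds relative to the event, half-open.
#' @param t0 time of the first sample of `trace` (seconds, default 0).
#' @param channelId,region passed to the returned [LFPEpochs-class].
#' @return An [LFPEpochs-class] with one row per event and
#'   `round(diff(window) * fs)` columns.
#' @export
epochTrace <- function(trace, fs, events, window, t0 = 0,
                       channelId = "ch1", region = "hippocampus") {
  nsamp <- round((window[2] - window[1]) * fs)
  n <- length(events)
  out <- matrix(NA_real_, n, nsamp)
  valid <- logical(n)
  for (i in seq_len(n)) {
    start <- floor((events[i] + window[1] - t0) * fs + 1e-9) + 1L
    idx <- start:(start + nsamp - 1L)
    if (idx[1] >= 1L && idx[nsamp] <= length(trace)) {
      out[i, ] <- trace[idx]
      valid[i] <- TRUE
    }
  }
  LFPEpochs(channelId, region, fs, out, window, valid)
}

#' Trim an epoch matrix to a sub-window
#'
#' @param epochs an [LFPEpochs-class].
#' @param window length-2 numeric, half-open sub-window in trial-relative
#'   seconds; must lie within the epoch window.
#' @return An [LFPEpochs-class] restricted to the sub-window.
#' @export
trimEpochs <- function(epochs, window = c(0, 2.5)) {
  w <- epochs@window
  if (window[1] < w[1] - 1e-9 || window[2] > w[2] + 1e-9)
    stop("requested window lies outside the epoch window")
  i0 <- round((window[1] - w[1]) * epochs@fs) + 1L
  n <- round((window[2] - window[1]) * epochs@fs)
  LFPEpochs(epochs@channelId, epochs@region, epochs@fs,
            epochs@samples[, i0:(i0 + n - 1L), drop = FALSE],
            window, epochs@validTrials)
}

.trialColumns <- c("trial_id", "load", "cat1", "cat2", "cat3",
                   "probe_category", "correct", "rt", "trial_start",
                   "picture_onset1", "picture_onset2", "picture_onset3",
                   "maintenance_onset", "probe_onset")

#' Write a Session to a plain-text fixture directory
#'
#' The fixture layout is `trials.csv` (trial table), `spikes.csv`
#' (`unit_id, region, channel_id, timestamp` long format), one
#' `lfp_<channelId>.csv` per channel (trials x time, no header), and
#' `manifest.json` recording channel metadata, windows, sampling rates and the
#' session metadata. Values are written at full double precision so a
#' write/read round trip is lossless.
#'
#' @param session a [Session-class].
#' @param dir directory to create/populate.
#' @return `dir`, invisibly.
#' @export
writeSessionFixture <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- session@trials
  write.csv(format(tr, digits = 17, scientific = FALSE, trim = TRUE),
            file.path(dir, "trials.csv"), row.names = FALSE, quote = FALSE)
  sp <- do.call(rbind, lapply(session@units, function(u) {
    if (length(u@timestamps) == 0L) return(NULL)
    data.frame(unit_id = u@unitId, region = u@region,
               channel_id = u@channelId, timestamp = u@timestamps)
  }))
  if (is.null(sp))
    sp <- data.frame(unit_id = character(), region = character(),
                     channel_id = character(), timestamp = numeric())
  write.csv(format(sp, digits = 17, scientific = FALSE, trim = TRUE),
            file.path(dir, "spikes.csv"), row.names = FALSE, quote = FALSE)
  chans <- lapply(session@lfp, function(ep) {
    fn <- sprintf("lfp_%s.csv", ep@channelId)
    write.table(format(ep@samples, digits = 17, scientific = FALSE,
                       trim = TRUE),
                file.path(dir, fn), row.names = FALSE, col.names = FALSE,
                sep = ",", quote = FALSE)
    list(channel_id = ep@channelId, region = ep@region, fs = ep@fs,
         window = ep@window, valid_trials = ep@validTrials, file = fn)
  })
  units_empty <- names(session@units)[
    vapply(session@units, function(u) length(u@timestamps) == 0L, logical(1))]
  unit_meta <- lapply(session@units, function(u)
    list(region = u@region, channel_id = u@channelId))
  jsonlite::write_json(
    list(channels = unname(chans), unit_meta = unit_meta,
         empty_units = units_empty, metadata = session@metadata),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a Session from a fixture directory
#'
#' Inverse of [writeSessionFixture()].
#'
#' @param dir fixture directory.
#' @return A [Session-class].
#' @export
readSessionFixture <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("not a session fixture: missing manifest.json")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  tr <- read.csv(file.path(dir, "trials.csv"))
  miss <- setdiff(c("trial_id", "load", "correct", "rt",
                    "maintenance_onset", "probe_onset"), names(tr))
  if (length(miss))
    stop("fixture trial table lacks columns: ", paste(miss, collapse = ", "))
  tr$correct <- as.logical(tr$correct)
  for (cc in intersect(c("trial_id", "load", "cat1", "cat2", "cat3",
                         "probe_category"), names(tr)))
    tr[[cc]] <- as.integer(tr[[cc]])
  for (cc in intersect(c("rt", "trial_start", "picture_onset1",
                         "picture_onset2", "picture_onset3",
                         "maintenance_onset", "probe_onset"), names(tr)))
    tr[[cc]] <- as.numeric(tr[[cc]])
  sp <- read.csv(file.path(dir, "spikes.csv"),
                 colClasses = c(unit_id = "character",
                                channel_id = "character"))
  units <- list()
  if (nrow(sp)) {
    for (uid in unique(sp$unit_id)) {
      s <- sp[sp$unit_id == uid, ]
      units[[uid]] <- SpikeTrain(uid, s$region[1], s$channel_id[1],
                                 sort(s$timestamp))
    }
  }
  um <- man$unit_meta
  for (uid in man$empty_units)
    units[[uid]] <- SpikeTrain(uid, um[[uid]]$region, um[[uid]]$channel_id,
                               numeric())
  lfp <- list()
  ch <- man$channels
  if (length(ch)) {
    for (i in seq_len(nrow(ch))) {
      m <- as.matrix(read.csv(file.path(dir, ch$file[i]), header = FALSE))
      dimnames(m) <- NULL
      lfp[[ch$channel_id[i]]] <- LFPEpochs(
        ch$channel_id[i], ch$region[i], ch$fs[i], m,
        as.numeric(ch$window[[i]]), as.logical(ch$valid_trials[[i]]))
    }
  }
  meta <- man$metadata
  if (is.null(meta)) meta <- list()
  Session(tr, lfp, units, as.list(meta))
}

#' Load a recording session
#'
#' @param path fixture directory (or NWB file for `format = "nwb"`).
#' @param format `"fixture"` for the package's CSV/JSON layout. `"nwb"`
#'   (DANDI 000673 layout) is declared for interface completeness but not
#'   implemented; requesting it raises an error.
#' @return A [Session-class].
#' @export
loadSession <- function(path, format = c("fixture", "nwb")) {
  format <- match.arg(format)
  if (format == "nwb")
    stop("NWB reading is not implemented; export the session to the CSV/JSON ",
         "fixture layout (see writeSessionFixture) and use format = 'fixture'")
  if (!file.exists(path)) stop("path does not exist: ", path)
  readSessionFixture(path)
}
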