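#' @import methods
#' @importFrom stats sd var cor median quantile rnorm runif rpois rbinom
#'   qnorm pnorm pt qt pf phyper rexp fft convolve complete.cases
#'   coef vcov logLik pchisq glm poisson predict p.adjust aggregate
#'   as.formula anova lm fitted setNames prcomp
#' @importFrom utils head tail read.csv write.csv
NULL

BRAIN_REGIONS <- c("hippocampus", "amygdala", "preSMA", "dACC", "vmPFC")

#' Epoched local field potential for one channel
#'
#' Holds the trial-by-time matrix of LFP samples (microvolts) for a single
#' microwire channel, aligned so that trial-relative time 0 is the onset of the
#' working-memory maintenance period. Sample windows are half-open
#' `[window[1], window[2])`.
#'
#' @slot channelId character scalar, channel identifier.
#' @slot region one of `"hippocampus"`, `"amygdala"`, `"preSMA"`, `"dACC"`,
#'   `"vmPFC"`.
#' @slot fs sampling rate in Hz (400 after preprocessing).
#' @slot samples numeric matrix, trials x time, in microvolts.
#' @slot window length-2 numeric, epoch window in seconds relative to
#'   maintenance onset.
#' @slot validTrials logical vector, one flag per trial row; `FALSE` marks
#'   trials rejected by artifact screening or falling outside the recording.
#' @exportClass LFPEpochs
setClass("LFPEpochs",
  representation(
    channelId = "character",
    region = "character",
    fs = "numeric",
    samples = "matrix",
    window = "numeric",
    validTrials = "logical"
  )
)

setValidity("LFPEpochs", function(object) {
  msg <- character()
  if (length(object@region) != 1L || !(object@region %in% BRAIN_REGIONS))
    msg <- c(msg, sprintf("region must be one of: %s",
                          paste(BRAIN_REGIONS, collapse = ", ")))
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be c(start, end) with start < end")
  if (length(object@validTrials) != nrow(object@samples))
    msg <- c(msg, "validTrials length must equal nrow(samples)")
  nexp <- round((object@window[2] - object@window[1]) * object@fs)
  if (ncol(object@samples) != nexp)
    msg <- c(msg, sprintf("samples has %d columns; window/fs imply %d",
                          ncol(object@samples), nexp))
  if (length(msg)) msg else TRUE
})

#' Spike train of a single sorted unit
#'
#' @slot unitId character scalar.
#' @slot region brain-region label (same vocabulary as [LFPEpochs-class]).
#' @slot channelId character scalar; the microwire the unit was detected on.
#' @slot timestamps numeric vector of spike times in seconds on the session
#'   clock, sorted ascending.
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(
    unitId = "character",
    region = "character",
    channelId = "character",
    timestamps = "numeric"
  )
)

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (!(object@region %in% BRAIN_REGIONS))
    msg <- c(msg, "unknown region label")
  if (is.unsorted(object@timestamps))
    msg <- c(msg, "timestamps must be sorted ascending")
  if (length(msg)) msg else TRUE
})

#' A recording session: trials, LFP epochs and spike trains
#'
#' The unit of analysis. `trials` is a data frame with one row per trial and
#' columns `trial_id`, `load` (1 or 3), `cat1..cat3` (encoded category ids,
#' `NA` padded for load 1), `probe_category`, `correct`, `rt` (seconds from
#' probe onset), and the session-clock event times `trial_start`,
#' `picture_onset1..3`, `maintenance_onset`, `probe_onset`.
#'
#' @slot trials data.frame, the trial table.
#' @slot lfp named list of [LFPEpochs-class], one per channel.
#' @slot units named list of [SpikeTrain-class], one per unit.
#' @slot metadata list (patient/session ids, generator seed, ...).
#' @exportClass Session
setClass("Session",
  representation(
    trials = "data.frame",
    lfp = "list",
    units = "list",
    metadata = "list"
  )
)

setValidity("Session", function(object) {
  msg <- character()
  tr <- object@trials
  need <- c("trial_id", "load", "correct", "rt", "maintenance_onset",
            "probe_onset")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    msg <- c(msg, sprintf("trial table lacks columns: %s",
                          paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (!all(tr$load %in% c(1L, 3L)))
      msg <- c(msg, "load must be 1 or 3")
    if (any(tr$rt <= 0, na.rm = TRUE))
      msg <- c(msg, "rt must be positive")
    if (any(tr$probe_onset <= tr$maintenance_onset))
      msg <- c(msg, "event times must increase within a trial")
    l3 <- tr$load == 3L
    if (any(l3) && all(c("cat1", "cat2", "cat3") %in% names(tr))) {
      cats <- as.matrix(tr[l3, c("cat1", "cat2", "cat3")])
      dup <- apply(cats, 1L, function(x) anyDuplicated(x[!is.na(x)]) > 0)
      if (any(dup))
        msg <- c(msg, "load-3 trials must carry three distinct categories")
    }
  }
  for (ep in object@lfp) {
    if (!is(ep, "LFPEpochs")) { msg <- c(msg, "lfp entries must be LFPEpochs"); break }
    if (nrow(ep@samples) != nrow(tr)) {
      msg <- c(msg, "LFPEpochs trial count must match the trial table"); break
    }
  }
  for (u in object@units)
    if (!is(u, "SpikeTrain")) { msg <- c(msg, "units entries must be SpikeTrain"); break }
  if (length(msg)) msg else TRUE
})

#' Bank of complex Morlet wavelets
#'
#' Forty analytic Morlet kernels with centre frequencies log-spaced from 2 to
#' 150 Hz and cycle counts log-spaced from 3 to 10, matched index-wise to the
#' frequencies, each normalised to unit energy.
#'
#' @slot freqs numeric vector of centre frequencies (Hz), strictly increasing.
#' @slot cycles numeric vector, same length, monotone non-decreasing.
#' @slot fs sampling rate the kernels were built for.
#' @slot kernels list of complex vectors (odd length, centred).
#' @exportClass MorletBank
setClass("MorletBank",
  representation(
    freqs = "numeric",
    cycles = "numeric",
    fs = "numeric",
    kernels = "list"
  )
)

setValidity("MorletBank", function(object) {
  msg <- character()
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(object@cycles) != length(object@freqs))
    msg <- c(msg, "cycles and freqs must have equal length")
  if (any(diff(object@cycles) < 0))
    msg <- c(msg, "cycles must be monotone non-decreasing")
  if (length(object@kernels) != length(object@freqs))
    msg <- c(msg, "one kernel per frequency required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LFPEpochs", function(object) {
  cat(sprintf("LFPEpochs '%s' (%s): %d trials x %d samples @ %g Hz, window [%g, %g) s, %d valid\n",
              object@channelId, object@region, nrow(object@samples),
              ncol(object@samples), object@fs, object@window[1],
              object@window[2], sum(object@validTrials)))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s' (%s, channel %s): %d spikes\n",
              object@unitId, object@region, object@channelId,
              length(object@timestamps)))
})

setMethod("show", "Session", function(object) {
  cat(sprintf("Session: %d trials (%d load 1 / %d load 3), %d LFP channels, %d units\n",
              nrow(object@trials), sum(object@trials$load == 1L),
              sum(object@trials$load == 3L), length(object@lfp),
              length(object@units)))
})

setMethod("show", "MorletBank", function(object) {
  cat(sprintf("MorletBank: %d wavelets, %.3g-%.3g Hz, %.3g-%.3g cycles @ %g Hz\n",
              length(object@freqs), min(object@freqs), max(object@freqs),
              min(object@cycles), max(object@cycles), object@fs))
})

#' Accessors for the core classes
#'
#' `trialInfo` returns the trial table of a [Session-class]; `lfpChannels` and
#' `spikeUnits` the named lists of epochs and units; `lfpSamples`,
#' `samplingRate`, `epochWindow`, `validTrials`, `channelRegion` the
#' corresponding [LFPEpochs-class] slots; `spikeTimes` the timestamps of a
#' [SpikeTrain-class].
#'
#' @param x a `Session`, `LFPEpochs` or `SpikeTrain` object.
#' @return The requested component.
#' @name accessors
#' @aliases trialInfo lfpChannels spikeUnits lfpSamples samplingRate
#'   epochWindow validTrials channelRegion spikeTimes
NULL

#' @rdname accessors
#' @export
trialInfo <- function(x) x@trials
#' @rdname accessors
#' @export
lfpChannels <- function(x) x@lfp
#' @rdname accessors
#' @export
spikeUnits <- function(x) x@units
#' @rdname accessors
#' @export
lfpSamples <- function(x) x@samples
#' @rdname accessors
#' @export
samplingRate <- function(x) x@fs
#' @rdname accessors
#' @export
epochWindow <- function(x) x@window
#' @rdname accessors
#' @export
validTrials <- function(x) x@validTrials
#' @rdname accessors
#' @export
channelRegion <- function(x) x@region
#' @rdname accessors
#' @export
spikeTimes <- function(x) x@timestamps

#' Construct an LFPEpochs object
#'
#' @param channelId,region,fs,samples,window,validTrials see
#'   [LFPEpochs-class].
#' @return A validated [LFPEpochs-class] object.
#' @export
LFPEpochs <- function(channelId, region, fs, samples, window,
                      validTrials = rep(TRUE, nrow(samples))) {
  new("LFPEpochs", channelId = as.character(channelId), region = region,
      fs = fs, samples = samples, window = window,
      validTrials = validTrials)
}

#' Construct a SpikeTrain object
#'
#' @param unitId,region,channelId,timestamps see [SpikeTrain-class].
#' @return A validated [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(unitId, region, channelId, timestamps) {
  new("SpikeTrain", unitId = as.character(unitId), region = region,
      channelId = as.character(channelId),
      timestamps = as.numeric(timestamps))
}

#' Construct a Session object
#'
#' @param trials,lfp,units,metadata see [Session-class].
#' @return A validated [Session-class] object.
#' @export
Session <- function(trials, lfp = list(), units = list(), metadata = list()) {
  new("Session", trials = trials, lfp = lfp, units = units,
      metadata = metadata)
}
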