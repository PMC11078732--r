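#' Remove action-potential transients from a raw trace
#'
#' Replaces the samples from 1 ms before to 2 ms after each spike onset with
#' the straight line joining the samples bounding that window, removing
#' spike-waveform leakage into low frequencies before filtering. Spikes from
#' all wires of the same bundle should be supplied, since a spike can appear
#' on neighbouring wires. Overlapping windows are merged; windows clipped by
#' the trace edges are clamped and filled with the nearest boundary value.
#'
#' @param trace numeric vector, raw recording.
#' @param fs sampling rate of `trace` in Hz.
#' @param spikeTimes numeric vector of spike onset times in seconds relative
#'   to the first sample of `trace`.
#' @param window interpolation window around each spike in seconds
#'   (default `c(-0.001, 0.002)`).
#' @return The trace with spike windows linearly interpolated; all other
#'   samples are bit-identical to the input.
#' @export
removeSpikeTransients <- function(trace, fs, spikeTimes,
                                  window = c(-0.001, 0.002)) {
  if (length(spikeTimes) == 0L) return(trace)
  n <- length(trace)
  a <- pmax(1L, floor((spikeTimes + window[1]) * fs) + 1L)
  b <- pmin(n, ceiling((spikeTimes + window[2]) * fs) + 1L)
  keep <- a <= n & b >= 1L
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(trace)
  o <- order(a)
  a <- a[o]; b <- b[o]
  # merge overlapping/adjacent windows
  ma <- a[1]; mb <- b[1]
  starts <- ends <- integer(0)
  for (i in seq_along(a)[-1]) {
    if (a[i] <= mb + 1L) mb <- max(mb, b[i])
    else { starts <- c(starts, ma); ends <- c(ends, mb); ma <- a[i]; mb <- b[i] }
  }
  starts <- c(starts, ma); ends <- c(ends, mb)
  out <- trace
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    lo <- s - 1L; hi <- e + 1L
    if (lo < 1L && hi > n) next
    if (lo < 1L) out[s:e] <- trace[hi]
    else if (hi > n) out[s:e] <- trace[lo]
    else {
      w <- (seq_len(e - s + 1L)) / (hi - lo)
      out[s:e] <- trace[lo] * (1 - w) + trace[hi] * w
    }
  }
  out
}

#' Low-pass filter, downsample to 400 Hz and notch line noise
#'
#' Zero-phase low-pass at 175 Hz, resampling to 400 Hz (plain decimation when
#' the rate ratio is an integer, polyphase resampling otherwise), then
#' zero-phase band-stop filters at 59.5-60.5 Hz and 119.5-120.5 Hz.
#'
#' @param trace numeric vector, continuous raw recording.
#' @param fsIn input sampling rate in Hz; must be at least 2 x 175 Hz.
#' @param fsOut output rate (default 400 Hz).
#' @param notches list of band-stop edges in Hz applied after downsampling.
#' @return A list with `trace` (filtered, at `fsOut`) and `fs`.
#' @export
filterDownsample <- function(trace, fsIn, fsOut = 400,
                             notches = list(c(59.5, 60.5), c(119.5, 120.5))) {
  if (fsIn < 2 * 175)
    stop("fsIn must be at least 350 Hz for the 175 Hz low-pass")
  y <- zeroPhaseFilter(trace, fsIn, "low", 175)
  if (fsIn %% fsOut == 0) {
    y <- y[seq(1L, length(y), by = fsIn / fsOut)]
  } else {
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    g <- gcd(round(fsIn), round(fsOut))
    y <- signal::resample(y, round(fsOut) / g, round(fsIn) / g)
  }
  for (nb in notches)
    if (nb[1] < fsOut / 2) y <- zeroPhaseFilter(y, fsOut, "stop", nb)
  list(trace = y, fs = fsOut)
}

#' Detect artifact and inter-ictal-discharge trials
#'
#' Deterministic screening of one channel's epochs: (amplitude rule) z-score
#' all samples of all trials pooled, cap at |6| SD, re-z-score the capped
#' data, and reject any trial with a sample beyond |4| SD; (jump rule)
#' z-score the lag-4 sample differences of the capped signal pooled the same
#' way and reject any trial with a difference beyond |10| SD. The mask is
#' invariant to affine rescaling of the whole channel. A zero-variance
#' channel retains all trials with a warning.
#'
#' @param epochs an [LFPEpochs-class] or a trials x time numeric matrix.
#' @param ampThresh,capSd,jumpThresh,jumpLag rule parameters.
#' @return A list with `valid` (logical per trial, combined with any existing
#'   `validTrials` mask), and `report` (counts per rule).
#' @export
detectArtifactTrials <- function(epochs, ampThresh = 4, capSd = 6,
                                 jumpThresh = 10, jumpLag = 4L) {
  x <- if (is(epochs, "LFPEpochs")) epochs@samples else epochs
  prior <- if (is(epochs, "LFPEpochs")) epochs@validTrials else
    rep(TRUE, nrow(x))
  use <- prior & apply(x, 1L, function(r) !anyNA(r))
  pool <- x[use, , drop = FALSE]
  mu <- mean(pool); s <- sd(as.vector(pool))
  if (!is.finite(s) || s == 0) {
    warning("zero-variance channel; all trials retained")
    return(list(valid = prior,
                report = list(amplitude_rejected = 0L, jump_rejected = 0L,
                              zero_variance = TRUE)))
  }
  z <- (x - mu) / s
  z <- pmin(pmax(z, -capSd), capSd)
  zp <- z[use, , drop = FALSE]
  z2 <- (z - mean(zp)) / sd(as.vector(zp))
  ampBad <- apply(abs(z2) > ampThresh, 1L, any)
  n <- ncol(z)
  d <- z[, (jumpLag + 1L):n, drop = FALSE] - z[, 1:(n - jumpLag), drop = FALSE]
  dp <- d[use, , drop = FALSE]
  sdd <- sd(as.vector(dp))
  jumpBad <- if (is.finite(sdd) && sdd > 0)
    apply(abs((d - mean(dp)) / sdd) > jumpThresh, 1L, any)
  else rep(FALSE, nrow(x))
  ampBad[is.na(ampBad)] <- FALSE
  jumpBad[is.na(jumpBad)] <- FALSE
  list(valid = prior & !ampBad & !jumpBad,
       report = list(amplitude_rejected = sum(ampBad & prior),
                     jump_rejected = sum(jumpBad & prior & !ampBad),
                     zero_variance = FALSE))
}
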