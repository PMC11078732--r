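#' Group session-clock spike times by trial, relative to an event
#'
#' @param timestamps spike times (seconds, session clock) or a
#'   [SpikeTrain-class].
#' @param events per-trial event times (e.g. maintenance onsets).
#' @param window half-open window in seconds relative to the event; spikes
#'   outside it are dropped (and counted).
#' @return A list with `times` (list per trial of event-relative spike
#'   times) and `nDropped`.
#' @export
spikesByTrial <- function(timestamps, events, window = c(0, 2.5)) {
  if (is(timestamps, "SpikeTrain")) timestamps <- timestamps@timestamps
  out <- vector("list", length(events))
  used <- 0L
  for (i in seq_along(events)) {
    rel <- timestamps - events[i]
    keep <- rel >= window[1] & rel < window[2]
    out[[i]] <- rel[keep]
    used <- used + sum(keep)
  }
  list(times = out, nDropped = length(timestamps) - used)
}

#' LFP phase at each spike time, per frequency
#'
#' Assigns each spike the phase of the nearest LFP sample within its trial,
#' for every frequency of a wavelet (or other) phase decomposition. Spikes in
#' trials flagged invalid, or outside the analysis window, are dropped and
#' counted.
#'
#' @param spikeTimes list per trial of event-relative spike times (see
#'   [spikesByTrial()]).
#' @param phase trials x freq x time array of phases (radians), e.g.
#'   `Arg(waveletTransform(...)$coef)`, or a trials x time matrix for a
#'   single band.
#' @param fs sampling rate of the phase array.
#' @param window half-open window the phase array covers, trial-relative
#'   seconds.
#' @param valid optional logical mask of usable trials.
#' @return A list with `phases` (spikes x freq matrix), `trial` (trial index
#'   per spike) and `nDropped`.
#' @export
spikePhases <- function(spikeTimes, phase, fs, window = c(0, 2.5),
                        valid = NULL) {
  if (length(dim(phase)) == 2L)
    phase <- array(phase, c(nrow(phase), 1L, ncol(phase)))
  ntr <- dim(phase)[1]; nf <- dim(phase)[2]; nt <- dim(phase)[3]
  if (is.null(valid)) valid <- rep(TRUE, ntr)
  ph <- list(); tri <- integer(0); dropped <- 0L
  for (i in seq_len(ntr)) {
    st <- spikeTimes[[i]]
    if (!length(st)) next
    if (!valid[i] || anyNA(phase[i, 1L, ])) { dropped <- dropped + length(st); next }
    idx <- round((st - window[1]) * fs) + 1L
    keep <- idx >= 1L & idx <= nt
    dropped <- dropped + sum(!keep)
    idx <- idx[keep]
    if (!length(idx)) next
    ph[[length(ph) + 1L]] <- matrix(phase[i, , idx], length(idx), nf,
                                    byrow = TRUE)
    tri <- c(tri, rep(i, length(idx)))
  }
  phases <- if (length(ph)) do.call(rbind, ph) else matrix(numeric(0), 0L, nf)
  list(phases = phases, trial = tri, nDropped = dropped)
}

.mvl <- function(phases) {
  # phases: spikes x freq; returns MVL per freq
  if (is.null(dim(phases))) phases <- matrix(phases, ncol = 1L)
  Mod(colMeans(exp(1i * phases)))
}

#' Spike-count-equalised mean vector length
#'
#' Computes the MVL of spike phases per frequency for each condition, after
#' subsampling spikes so that every condition contributes the same number
#' (the minimum across conditions); the subsampling is repeated `nRep` times
#' and the MVLs averaged. Conditions below `minSpikes` exclude the pair.
#'
#' @param phasesByCondition named list; each element a spikes x freq phase
#'   matrix (or vector for one band).
#' @param minSpikes minimum spikes per condition (50 for load contrasts, 10
#'   for preferred/non-preferred contrasts in category cells).
#' @param nRep subsampling repetitions (default 500).
#' @return A list with `mvl` (condition x freq matrix), `nSpikesUsed`; or, if
#'   a condition is under-sampled, `excluded = TRUE` with `reason`.
#' @export
mvlSubsampled <- function(phasesByCondition, minSpikes = 50L, nRep = 500L) {
  asMat <- function(x) if (is.null(dim(x))) matrix(x, ncol = 1L) else x
  phasesByCondition <- lapply(phasesByCondition, asMat)
  ns <- vapply(phasesByCondition, nrow, integer(1))
  if (any(ns < minSpikes))
    return(list(excluded = TRUE,
                reason = sprintf("condition '%s' has %d < %d spikes",
                                 names(ns)[which.min(ns)], min(ns), minSpikes),
                nSpikes = ns))
  nSub <- min(ns)
  nf <- ncol(phasesByCondition[[1]])
  mvlOne <- function(phm) {
    if (nrow(phm) == nSub) return(unname(.mvl(phm)))
    acc <- numeric(nf)
    for (r in seq_len(nRep))
      acc <- acc + .mvl(phm[sample.int(nrow(phm), nSub), , drop = FALSE])
    unname(acc / nRep)
  }
  mvl <- do.call(rbind, lapply(phasesByCondition, mvlOne))
  dimnames(mvl) <- list(names(phasesByCondition), NULL)
  list(mvl = mvl, nSpikesUsed = nSub, excluded = FALSE)
}

#' Jitter-surrogate z-scored MVL
#'
#' Builds a surrogate MVL distribution by re-drawing each spike's time
#' uniformly within its own trial's analysis window (destroying phase locking
#' at all analysed frequencies while preserving spike counts and trial
#' assignment), fits a normal distribution, and z-scores the raw MVL per
#' frequency. If the raw MVL was computed on a spike subsample, pass
#' `subsampleTo` so surrogates are computed at the same count.
#'
#' @param rawMvl numeric vector, raw MVL per frequency.
#' @param spikeTimes list per trial of event-relative spike times (the
#'   condition's spikes).
#' @param phase trials x freq x time phase array (or trials x time matrix).
#' @param fs,window,valid as in [spikePhases()].
#' @param nSurrogates jitter surrogates (default 500).
#' @param subsampleTo spike count used for the raw MVL; `NULL` for all.
#' @param nRepSub subsample repetitions per surrogate when `subsampleTo` is
#'   below the spike count.
#' @return A list with `z`, `mu`, `sd` (each per frequency).
#' @export
jitterZ <- function(rawMvl, spikeTimes, phase, fs, window = c(0, 2.5),
                    valid = NULL, nSurrogates = 500L, subsampleTo = NULL,
                    nRepSub = 20L) {
  if (length(dim(phase)) == 2L)
    phase <- array(phase, c(nrow(phase), 1L, ncol(phase)))
  counts <- lengths(spikeTimes)
  surr <- vapply(seq_len(nSurrogates), function(s) {
    jit <- lapply(seq_along(spikeTimes), function(i)
      runif(counts[i], window[1], window[2]))
    sp <- spikePhases(jit, phase, fs, window, valid)
    n <- nrow(sp$phases)
    if (!is.null(subsampleTo) && subsampleTo < n) {
      rowMeans(vapply(seq_len(nRepSub), function(r)
        .mvl(sp$phases[sample.int(n, subsampleTo), , drop = FALSE]),
        numeric(dim(phase)[2])))
    } else .mvl(sp$phases)
  }, numeric(dim(phase)[2]))
  surr <- matrix(surr, nrow = dim(phase)[2])
  mu <- rowMeans(surr)
  sdv <- apply(surr, 1L, sd)
  if (any(!is.finite(sdv) | sdv == 0))
    stop("degenerate jitter surrogate distribution")
  list(z = (rawMvl - mu) / sdv, mu = mu, sd = sdv)
}

#' Condition contrast of z-scored coherence spectra
#'
#' Paired per-frequency differences of z-MVL between two conditions across
#' neuron-channel pairs, with cluster-based permutation correction over the
#' frequency axis; the cluster alpha can be Bonferroni-adjusted for the test
#' family.
#'
#' @param zA,zB pairs x frequencies matrices of z-MVL (same pairs, equalised
#'   spike counts).
#' @param freqs frequency grid (Hz) for reporting.
#' @param nPerm permutations for the cluster test.
#' @param alphaCluster per-direction cluster alpha (0.025), divided by
#'   `bonferroniN` if given.
#' @param bonferroniN size of the test family, or `NULL`.
#' @return A list with `meanDiff` per frequency, `clusters` (with frequency
#'   ranges attached) and the cluster `tValues`.
#' @export
sfcContrast <- function(zA, zB, freqs = NULL, nPerm = 10000L,
                        alphaCluster = 0.025, bonferroniN = NULL) {
  if (!all(dim(zA) == dim(zB))) stop("condition spectra must be paired")
  if (!is.null(bonferroniN)) alphaCluster <- alphaCluster / bonferroniN
  d <- zA - zB
  res <- clusterPermFreq(d, nPerm = nPerm, alphaCluster = alphaCluster)
  cl <- res$clusters
  if (!is.null(freqs) && nrow(cl)) {
    cl$freqLo <- freqs[cl$start]
    cl$freqHi <- freqs[cl$end]
  }
  list(meanDiff = colMeans(d), clusters = cl, tValues = res$tValues,
       alphaCluster = alphaCluster)
}

#' Preferred/non-preferred contrast split by gamma amplitude
#'
#' Median-splits spikes by the gamma amplitude at their time, then computes
#' the spike-count-equalised MVL contrast between two conditions separately
#' within the high- and low-amplitude halves.
#'
#' @param phases spikes x freq phase matrix.
#' @param gammaAmp gamma amplitude at each spike time (same spike order).
#' @param condition factor with two levels per spike (e.g. preferred /
#'   non-preferred).
#' @param minSpikes,nRep passed to [mvlSubsampled()].
#' @return A list with `high` and `low`, each the condition-level MVL result
#'   plus `diff` (level1 - level2 per frequency), and the split `threshold`.
#' @export
gammaAmplitudeSplitSfc <- function(phases, gammaAmp, condition,
                                   minSpikes = 10L, nRep = 100L) {
  if (is.null(dim(phases))) phases <- matrix(phases, ncol = 1L)
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2L, nrow(phases) == length(gammaAmp),
            length(condition) == length(gammaAmp))
  thr <- median(gammaAmp)
  hi <- gammaAmp > thr
  one <- function(sel) {
    byCond <- split(seq_len(nrow(phases))[sel], condition[sel])
    r <- mvlSubsampled(lapply(byCond, function(i)
      phases[i, , drop = FALSE]), minSpikes, nRep)
    if (!isTRUE(r$excluded)) r$diff <- r$mvl[1, ] - r$mvl[2, ]
    r
  }
  list(high = one(hi), low = one(!hi), threshold = thr)
}
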