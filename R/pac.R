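#' Tort modulation index of a phase/amplitude pair
#'
#' Bins the phase stream into `nBins` equal bins over (-pi, pi], computes the
#' mean amplitude per bin, normalises the bin means to a distribution `p`, and
#' returns `MI = (log N - H(p)) / log N` with `H` the Shannon entropy. MI is 0
#' for a flat amplitude-by-phase profile and 1 when all amplitude mass falls
#' in a single bin; it is invariant to positive rescaling of the amplitude
#' stream.
#'
#' @param phase numeric vector of phases in radians (any branch; wrapped
#'   internally), typically trial-concatenated.
#' @param amplitude numeric vector of non-negative amplitudes, same length.
#' @param nBins number of phase bins (default 18).
#' @return A list with `mi`, `profile` (normalised bin means), `binCenters`
#'   and `preferredPhase` (centre of the argmax bin, radians).
#' @export
modulationIndex <- function(phase, amplitude, nBins = 18L) {
  stopifnot(length(phase) == length(amplitude))
  ok <- is.finite(phase) & is.finite(amplitude)
  phase <- phase[ok]; amplitude <- amplitude[ok]
  idx <- .phaseBin(phase, nBins)
  cnt <- tabulate(idx, nBins)
  if (any(cnt == 0L))
    stop("empty phase bin(s): ", paste(which(cnt == 0L), collapse = ", "))
  sums <- as.vector(rowsum(amplitude, idx))
  .miFromProfile(sums / cnt, nBins)
}

.phaseBin <- function(phase, nBins) {
  ph <- (phase + pi) %% (2 * pi)        # [0, 2pi), pi maps to 0-edge
  idx <- floor(ph / (2 * pi) * nBins) + 1L
  pmin.int(idx, nBins)
}

.miFromProfile <- function(means, nBins) {
  p <- means / sum(means)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  centers <- -pi + (seq_len(nBins) - 0.5) * 2 * pi / nBins
  list(mi = (log(nBins) - h) / log(nBins), profile = p,
       binCenters = centers, preferredPhase = centers[which.max(p)])
}

# Precompute, for phase-trial i and amplitude-trial j, the per-bin amplitude
# sums A[bin, i, j] and phase-bin counts C[bin, i]. Any trial pairing's MI is
# then O(bins x trials), which makes the 200 trial-shuffle surrogates cheap.
# Algebraically identical to binning the concatenated streams directly.
.pairingSums <- function(phaseTrials, ampTrials, nBins) {
  ntr <- nrow(phaseTrials)
  A <- array(0, c(nBins, ntr, ntr))
  C <- matrix(0L, nBins, ntr)
  tA <- t(ampTrials)
  for (i in seq_len(ntr)) {
    idx <- .phaseBin(phaseTrials[i, ], nBins)
    C[, i] <- tabulate(idx, nBins)
    s <- rowsum(tA, idx)
    A[as.integer(rownames(s)), i, ] <- s
  }
  list(A = A, C = C)
}

.pairingMI <- function(ps, pairing, nBins) {
  ntr <- length(pairing)
  Amat <- matrix(ps$A, nBins)   # columns indexed by (amp trial - 1) * ntr + phase trial
  cols <- (pairing - 1L) * ntr + seq_len(ntr)
  sums <- rowSums(Amat[, cols, drop = FALSE])
  cnt <- rowSums(ps$C)
  if (any(cnt == 0L))
    stop("empty phase bin(s): ", paste(which(cnt == 0L), collapse = ", "))
  .miFromProfile(sums / cnt, nBins)
}

# random derangement by rejection (no trial pairs with itself)
.derangement <- function(n) {
  if (n < 2L) stop("derangement needs n >= 2")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Surrogate-normalised modulation index
#'
#' Computes the raw MI on the trial-concatenated phase and amplitude streams,
#' then builds `nSurrogates` surrogate MIs by pairing the phase stream of each
#' trial with the amplitude stream of a different trial (a random derangement,
#' so no trial is paired with itself). A normal distribution is fitted to the
#' surrogates (moment estimators) and used to z-transform the raw MI.
#'
#' @param phaseTrials,ampTrials trials x time matrices of phase (radians) and
#'   amplitude; rows are trials. At least 10 trials are required.
#' @param nSurrogates number of trial-shuffle surrogates (default 200).
#' @param nBins phase bins for the MI.
#' @return A list with `z`, `rawMI`, `surrogateMu`, `surrogateSd`,
#'   `preferredPhase`, `profile` and `nTrials`.
#' @export
surrogateZ <- function(phaseTrials, ampTrials, nSurrogates = 200L,
                       nBins = 18L) {
  stopifnot(all(dim(phaseTrials) == dim(ampTrials)))
  ok <- !apply(phaseTrials, 1L, anyNA) & !apply(ampTrials, 1L, anyNA)
  phaseTrials <- phaseTrials[ok, , drop = FALSE]
  ampTrials <- ampTrials[ok, , drop = FALSE]
  ntr <- nrow(phaseTrials)
  if (ntr < 10L) stop("at least 10 trials are required")
  ps <- .pairingSums(phaseTrials, ampTrials, nBins)
  raw <- .pairingMI(ps, seq_len(ntr), nBins)
  surr <- vapply(seq_len(nSurrogates), function(s)
    .pairingMI(ps, .derangement(ntr), nBins)$mi, numeric(1))
  mu <- mean(surr); sdv <- sd(surr)
  if (!is.finite(sdv) || sdv == 0) stop("degenerate surrogate distribution")
  list(z = (raw$mi - mu) / sdv, rawMI = raw$mi, surrogateMu = mu,
       surrogateSd = sdv, preferredPhase = raw$preferredPhase,
       profile = raw$profile, nTrials = ntr)
}

#' Comodulogram of surrogate-normalised PAC
#'
#' Grid of z-scored modulation indices over phase centre frequencies 2-14 Hz
#' (step 2, fixed 2 Hz bandwidth) by amplitude centre frequencies 30-150 Hz
#' (step 5), the amplitude bandwidth equalling twice the phase centre
#' frequency so that modulation side peaks are retained.
#'
#' @slot zMI,rawMI,surrogateMu,surrogateSd numeric phase x amplitude matrices.
#' @slot phaseCenters,ampCenters numeric grids in Hz.
#' @slot condition label (`"all"`, `"load1"`, `"load3"`).
#' @slot nTrials trials used.
#' @exportClass Comodulogram
setClass("Comodulogram",
  representation(zMI = "matrix", rawMI = "matrix", surrogateMu = "matrix",
                 surrogateSd = "matrix", phaseCenters = "numeric",
                 ampCenters = "numeric", condition = "character",
                 nTrials = "integer"))

setValidity("Comodulogram", function(object) {
  msg <- character()
  if (!all(dim(object@zMI) == c(length(object@phaseCenters),
                                length(object@ampCenters))))
    msg <- c(msg, "zMI must be phaseCenters x ampCenters")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Comodulogram", function(object) {
  cat(sprintf("Comodulogram (%s): %d x %d, max z = %.2f at (%g Hz, %g Hz), %d trials\n",
              object@condition, nrow(object@zMI), ncol(object@zMI),
              max(object@zMI),
              object@phaseCenters[which(object@zMI == max(object@zMI),
                                        arr.ind = TRUE)[1, 1]],
              object@ampCenters[which(object@zMI == max(object@zMI),
                                      arr.ind = TRUE)[1, 2]],
              object@nTrials))
})

#' Compute a PAC comodulogram for one channel
#'
#' @param epochs an [LFPEpochs-class] with padding around `trim`.
#' @param trials optional logical mask of trials to use (combined with the
#'   epochs' valid-trial mask).
#' @param phaseCenters,ampCenters frequency grids in Hz.
#' @param phaseBandwidth fixed phase bandwidth in Hz (total width).
#' @param nSurrogates trial-shuffle surrogates per cell.
#' @param nBins phase bins for the MI.
#' @param trim analysis window, seconds.
#' @param condition label stored in the result.
#' @return A [Comodulogram-class].
#' @export
computeComodulogram <- function(epochs, trials = NULL,
                                phaseCenters = seq(2, 14, 2),
                                ampCenters = seq(30, 150, 5),
                                phaseBandwidth = 2, nSurrogates = 200L,
                                nBins = 18L, trim = c(0, 2.5),
                                condition = "all") {
  mask <- epochs@validTrials
  if (!is.null(trials)) mask <- mask & trials
  np <- length(phaseCenters); na <- length(ampCenters)
  zm <- rm_ <- mu <- sdv <- matrix(NA_real_, np, na)
  for (i in seq_len(np)) {
    pc <- phaseCenters[i]
    ph <- hilbertPhaseAmp(epochs, c(pc - phaseBandwidth / 2,
                                    pc + phaseBandwidth / 2), trim)$phase
    ph <- ph[mask, , drop = FALSE]
    for (j in seq_len(na)) {
      ac <- ampCenters[j]
      band <- c(max(0.5, ac - pc), min(epochs@fs / 2 - 1e-6, ac + pc))
      am <- hilbertPhaseAmp(epochs, band, trim)$amplitude
      am <- am[mask, , drop = FALSE]
      res <- surrogateZ(ph, am, nSurrogates, nBins)
      zm[i, j] <- res$z; rm_[i, j] <- res$rawMI
      mu[i, j] <- res$surrogateMu; sdv[i, j] <- res$surrogateSd
    }
  }
  new("Comodulogram", zMI = zm, rawMI = rm_, surrogateMu = mu,
      surrogateSd = sdv, phaseCenters = phaseCenters, ampCenters = ampCenters,
      condition = condition, nTrials = sum(mask))
}

#' Select channels with significant theta-gamma PAC
#'
#' Averages the z-comodulogram (computed on all subsampled trials pooled over
#' load) over the theta (phase centres within 3-7 Hz) x high-gamma
#' (amplitude centres within 70-140 Hz) cells, and separately over
#' theta x low-gamma (30-55 Hz) cells; a channel is significant in a band if
#' the mean z exceeds the standard-normal 95th percentile (1.64, right-sided).
#'
#' @param comodulograms named list of [Comodulogram-class], one per channel.
#' @param thetaRange,highGamma,lowGamma band limits in Hz.
#' @param threshold z threshold; default `qnorm(0.95)`.
#' @return A data frame with one row per channel: mean z per band, per-band
#'   significance, and `significant` (either band).
#' @export
selectPacChannels <- function(comodulograms, thetaRange = c(3, 7),
                              highGamma = c(70, 140), lowGamma = c(30, 55),
                              threshold = qnorm(0.95)) {
  rows <- lapply(names(comodulograms), function(ch) {
    cm <- comodulograms[[ch]]
    pidx <- cm@phaseCenters >= thetaRange[1] & cm@phaseCenters <= thetaRange[2]
    hidx <- cm@ampCenters >= highGamma[1] & cm@ampCenters <= highGamma[2]
    lidx <- cm@ampCenters >= lowGamma[1] & cm@ampCenters <= lowGamma[2]
    zh <- mean(cm@zMI[pidx, hidx])
    zl <- mean(cm@zMI[pidx, lidx])
    data.frame(channel_id = ch, meanZ_highGamma = zh, meanZ_lowGamma = zl,
               sig_highGamma = zh > threshold, sig_lowGamma = zl > threshold,
               significant = zh > threshold || zl > threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Compare an observed selection count to a surrogate null
#'
#' Right-sided permutation p for a count of selected channels (or neurons)
#' against surrogate counts, with the (b+1)/(m+1) correction; significance is
#' judged at the 99th percentile of the null.
#'
#' @param observed observed count.
#' @param surrogateCounts numeric vector of null counts.
#' @param percentile null percentile for the significance call (default 0.99).
#' @return A list with `p`, `critical` (null percentile) and `significant`.
#' @export
proportionAboveNull <- function(observed, surrogateCounts, percentile = 0.99) {
  p <- (sum(surrogateCounts >= observed) + 1) / (length(surrogateCounts) + 1)
  crit <- quantile(surrogateCounts, percentile, names = FALSE, type = 1)
  list(p = p, critical = crit, significant = observed > crit)
}

#' Load contrast of PAC across significant channels
#'
#' Paired permutation t-test of per-channel z-MI between load 3 and load 1
#' (both computed on equal trial counts), run within each brain area, with
#' Benjamini-Hochberg FDR correction across the five areas.
#'
#' @param zLoad1,zLoad3 numeric vectors, one z-MI per channel and load.
#' @param areas factor/character of area labels per channel.
#' @param nPerm permutations for the paired test.
#' @param q FDR level across areas.
#' @return Data frame per area: mean difference (load3 - load1), `t`, `p`,
#'   `p_fdr`, `significant`.
#' @export
loadContrast <- function(zLoad1, zLoad3, areas = rep("hippocampus",
                                                     length(zLoad1)),
                         nPerm = 10000L, q = 0.05) {
  stopifnot(length(zLoad1) == length(zLoad3))
  if (length(zLoad1) < 2L) stop("at least 2 channels are required")
  areas <- as.character(areas)
  rows <- lapply(unique(areas), function(a) {
    i <- areas == a
    if (sum(i) < 2L)
      return(data.frame(area = a, meanDiff = NA_real_, t = NA_real_,
                        p = NA_real_))
    tt <- permTTest(zLoad3[i], zLoad1[i], paired = TRUE, nPerm = nPerm)
    data.frame(area = a, meanDiff = mean(zLoad3[i] - zLoad1[i]), t = tt$t,
               p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < q
  out
}

#' Single-trial theta-gamma PAC estimates
#'
#' Raw (un-normalised) MI computed within each trial's analysis window for a
#' significant PAC channel, for trial-by-trial models against firing rate or
#' reaction time. Invalid trials, or trials whose short window leaves a phase
#' bin empty, yield `NA`.
#'
#' @param epochs an [LFPEpochs-class].
#' @param thetaBand,gammaBand phase and amplitude bands in Hz.
#' @param nBins phase bins.
#' @param trim analysis window.
#' @return Numeric vector, one MI (or `NA`) per trial row.
#' @export
singleTrialPac <- function(epochs, thetaBand = c(3, 7),
                           gammaBand = c(70, 140), nBins = 18L,
                           trim = c(0, 2.5)) {
  ph <- hilbertPhaseAmp(epochs, thetaBand, trim)$phase
  am <- hilbertPhaseAmp(epochs, gammaBand, trim)$amplitude
  vapply(seq_len(nrow(ph)), function(i) {
    if (!epochs@validTrials[i] || anyNA(ph[i, ])) return(NA_real_)
    tryCatch(modulationIndex(ph[i, ], am[i, ], nBins)$mi,
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Theta-cycle waveform asymmetries
#'
#' Per theta cycle, the peak-to-trough asymmetry is the fraction of the cycle
#' spent in its peak half (between the rising and falling zero crossings) and
#' the rise-to-decay asymmetry the fraction spent rising (trough to peak);
#' both are 0.5 for a symmetric oscillation. Values are averaged over cycles
#' within each trial; trials with fewer than `minCycles` cycles yield `NA`.
#' Time-reversal flips the rise-decay asymmetry about 0.5.
#'
#' @param epochs an [LFPEpochs-class] or trials x time matrix.
#' @param band theta band in Hz for the initial band-pass; `NULL` to analyse
#'   the signal as supplied.
#' @param trim analysis window (ignored for bare matrices).
#' @param minCycles minimum complete cycles per trial.
#' @param fs sampling rate when `epochs` is a matrix.
#' @return Data frame per trial: `pt` (peak-trough), `rd` (rise-decay),
#'   `nCycles`.
#' @export
cycleAsymmetry <- function(epochs, band = c(3, 7), trim = c(0, 2.5),
                           minCycles = 3L, fs = NULL) {
  if (is(epochs, "LFPEpochs")) {
    fs <- epochs@fs
    x <- if (is.null(band)) trimEpochs(epochs, trim)@samples
         else {
           h <- hilbertPhaseAmp(epochs, band, trim)
           # real band-passed signal: amplitude * cos(phase)
           h$amplitude * cos(h$phase)
         }
  } else {
    x <- if (is.null(band)) epochs else zeroPhaseFilter(epochs, fs, "pass", band)
  }
  res <- t(vapply(seq_len(nrow(x)), function(i)
    .cycleStats(x[i, ], fs, minCycles), numeric(3)))
  data.frame(trial = seq_len(nrow(x)), pt = res[, 1], rd = res[, 2],
             nCycles = as.integer(res[, 3]))
}

.cycleStats <- function(y, fs, minCycles) {
  if (anyNA(y)) return(c(NA, NA, 0))
  y <- y - mean(y)
  s <- sign(y); s[s == 0] <- 1
  up <- which(diff(s) > 0) + 1L    # rising zero crossings
  dn <- which(diff(s) < 0) + 1L    # falling zero crossings
  if (length(up) < 2L) return(c(NA, NA, 0))
  pt <- rd <- numeric(0)
  for (k in seq_len(length(up) - 1L)) {
    a <- up[k]; b <- up[k + 1L]
    f <- dn[dn > a & dn < b]
    if (length(f) != 1L) next
    peakT <- a - 1L + which.max(y[a:f])
    trough <- f - 1L + which.min(y[f:b])
    peakHalf <- f - a           # samples above zero
    troughHalf <- b - f         # samples below zero
    pt <- c(pt, peakHalf / (peakHalf + troughHalf))
    # rise/decay from extrema: decay = peak -> trough, rise = trough -> next peak
    f2 <- dn[dn > b]
    nextPeak <- if (length(f2)) b - 1L + which.max(y[b:f2[1]]) else NA
    if (!is.na(nextPeak)) {
      decay <- trough - peakT
      riseT <- nextPeak - trough
      if (decay > 0 && riseT > 0) rd <- c(rd, riseT / (riseT + decay))
    }
  }
  n <- length(pt)
  if (n < minCycles) return(c(NA, NA, n))
  c(mean(pt), if (length(rd)) mean(rd) else NA, n)
}

#' Detect theta-gamma nesting in the raw waveform
#'
#' Finds, within each occurrence of the preferred theta-phase bin, the time of
#' maximal gamma amplitude; averages 500-ms raw-LFP windows centred on those
#' times; and calls the channel nested if at least three local maxima of the
#' average waveform fall within a 45-ms window (three cycles at 70 Hz) around
#' its centre.
#'
#' @param rawEpochs an [LFPEpochs-class] of unfiltered data whose window
#'   extends at least 250 ms beyond the analysis window on both sides.
#' @param thetaPhase,gammaAmp trials x time matrices over `trim` (e.g. from
#'   [hilbertPhaseAmp()] with the 3-7 Hz and 70-140 Hz bands).
#' @param preferredBin integer in `1:nBins`, the preferred phase bin.
#' @param nBins phase bins used to define the preferred bin.
#' @param trim analysis window the phase/amplitude matrices cover.
#' @param winLen averaging window length in seconds (default 0.5).
#' @param centralWin width of the central window for counting maxima
#'   (default 0.045 s).
#' @param minWindows below this many windows the call is flagged unreliable.
#' @return A list with `nested`, `meanWaveform`, `nWindows`,
#'   `nCentralMaxima`, `reliable`.
#' @export
detectNesting <- function(rawEpochs, thetaPhase, gammaAmp, preferredBin,
                          nBins = 18L, trim = c(0, 2.5), winLen = 0.5,
                          centralWin = 0.045, minWindows = 10L) {
  fs <- rawEpochs@fs
  half <- round(winLen / 2 * fs)
  segs <- list()
  for (tr in seq_len(nrow(thetaPhase))) {
    if (!rawEpochs@validTrials[tr] || anyNA(thetaPhase[tr, ])) next
    inBin <- .phaseBin(thetaPhase[tr, ], nBins) == preferredBin
    r <- rle(inBin)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- starts[k]:ends[k]
      tmax <- seg[which.max(gammaAmp[tr, seg])]
      # index into the raw epoch window
      raw0 <- round((trim[1] - rawEpochs@window[1]) * fs)
      c0 <- raw0 + tmax
      if (c0 - half >= 1L && c0 + half <= ncol(rawEpochs@samples))
        segs[[length(segs) + 1L]] <-
          rawEpochs@samples[tr, (c0 - half):(c0 + half)]
    }
  }
  nW <- length(segs)
  if (nW == 0L)
    return(list(nested = FALSE, meanWaveform = NULL, nWindows = 0L,
                nCentralMaxima = 0L, reliable = FALSE))
  wf <- colMeans(do.call(rbind, segs))
  d <- diff(wf)
  locmax <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  mid <- half + 1L
  cw <- round(centralWin / 2 * fs)
  nc <- sum(abs(locmax - mid) <= cw)
  list(nested = nc >= 3L, meanWaveform = wf, nWindows = nW,
       nCentralMaxima = nc, reliable = nW >= minWindows)
}
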