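#' Band-limited instantaneous phase and amplitude
#'
#' Zero-phase FIR band-pass of each trial followed by the Hilbert transform.
#' Trials are filtered on the full (padded) epoch window and only then trimmed
#' to `trim`, so filter edge artifacts fall outside the analysis window. The
#' phase convention is radians in (-pi, pi] with 0 at the oscillation peak
#' (cosine convention).
#'
#' @param epochs an [LFPEpochs-class] (ideally with at least 0.5 s of padding
#'   on each side of `trim`) or a trials x time matrix (then `fs` and
#'   `window` are required).
#' @param band `c(f1, f2)` pass band in Hz; must lie below Nyquist.
#' @param trim half-open analysis window in trial-relative seconds.
#' @param fs,window used when `epochs` is a bare matrix.
#' @return A list with `phase` and `amplitude` (trials x time matrices over
#'   `trim`), `fs`, `window` and `band`.
#' @export
hilbertPhaseAmp <- function(epochs, band, trim = c(0, 2.5),
                            fs = NULL, window = NULL) {
  if (is(epochs, "LFPEpochs")) {
    x <- epochs@samples; fs <- epochs@fs; window <- epochs@window
  } else x <- epochs
  if (band[2] >= fs / 2)
    stop("band upper edge must be below the Nyquist frequency")
  if (window[1] > trim[1] - 0.5 + 1e-9 || window[2] < trim[2] + 0.5 - 1e-9)
    warning("less than 0.5 s of filter padding around the analysis window")
  bad <- apply(x, 1L, anyNA)
  xf <- x
  xf[bad, ] <- 0
  y <- zeroPhaseFilter(xf, fs, "pass", band)
  a <- analyticSignal(y)
  i0 <- round((trim[1] - window[1]) * fs) + 1L
  n <- round((trim[2] - trim[1]) * fs)
  a <- a[, i0:(i0 + n - 1L), drop = FALSE]
  ph <- Arg(a); am <- Mod(a)
  ph[bad, ] <- NA; am[bad, ] <- NA
  list(phase = ph, amplitude = am, fs = fs, window = trim, band = band)
}

#' Build a bank of complex Morlet wavelets
#'
#' Centre frequencies and cycle counts are log-spaced (defaults: 40 wavelets,
#' 2-150 Hz, 3-10 cycles) and matched index-wise; each kernel is normalised to
#' unit energy so amplitudes are comparable across frequencies before
#' z-scoring.
#'
#' @param fs sampling rate in Hz.
#' @param nFreqs number of wavelets.
#' @param freqRange,cycleRange ranges for the log-spaced grids.
#' @param cycles optional explicit cycle count (recycled), overriding
#'   `cycleRange`; e.g. `cycles = 7` for the fixed-cycle gamma bank.
#' @return A [MorletBank-class].
#' @export
morletBank <- function(fs, nFreqs = 40L, freqRange = c(2, 150),
                       cycleRange = c(3, 10), cycles = NULL) {
  freqs <- exp(seq(log(freqRange[1]), log(freqRange[2]), length.out = nFreqs))
  cyc <- if (is.null(cycles))
    exp(seq(log(cycleRange[1]), log(cycleRange[2]), length.out = nFreqs))
  else rep_len(cycles, nFreqs)
  kernels <- lapply(seq_len(nFreqs), function(i) {
    sdt <- cyc[i] / (2 * pi * freqs[i])
    half <- ceiling(4 * sdt * fs)
    t <- seq(-half, half) / fs
    k <- exp(2i * pi * freqs[i] * t) * exp(-t^2 / (2 * sdt^2))
    k / sqrt(sum(Mod(k)^2))
  })
  new("MorletBank", freqs = freqs, cycles = cyc, fs = fs, kernels = kernels)
}

#' Continuous wavelet transform of epoched data
#'
#' Convolves each trial with every kernel of the bank (reflection padding,
#' centred), then trims to the analysis window. Phase is the argument and
#' amplitude the modulus of the coefficients.
#'
#' @param epochs an [LFPEpochs-class] or trials x time matrix.
#' @param bank a [MorletBank-class] built for the same sampling rate.
#' @param trim half-open analysis window in trial-relative seconds; `NULL`
#'   keeps the full epoch.
#' @param fs,window used when `epochs` is a bare matrix.
#' @return A list with `coef` (complex array trial x freq x time), `freqs`,
#'   `fs` and `window`.
#' @export
waveletTransform <- function(epochs, bank, trim = c(0, 2.5),
                             fs = NULL, window = NULL) {
  if (is(epochs, "LFPEpochs")) {
    x <- epochs@samples; fs <- epochs@fs; window <- epochs@window
  } else {
    x <- epochs
    if (is.null(window)) window <- c(0, ncol(x) / fs)
  }
  if (abs(fs - bank@fs) > 1e-9)
    stop("wavelet bank was built for fs = ", bank@fs)
  bad <- apply(x, 1L, anyNA)
  x[bad, ] <- 0
  if (is.null(trim)) trim <- window
  i0 <- round((trim[1] - window[1]) * fs) + 1L
  nt <- round((trim[2] - trim[1]) * fs)
  nf <- length(bank@freqs)
  out <- array(NA_complex_, c(nrow(x), nf, nt))
  for (f in seq_len(nf)) {
    y <- convSame(x, bank@kernels[[f]])
    out[, f, ] <- y[, i0:(i0 + nt - 1L), drop = FALSE]
  }
  out[bad, , ] <- NA
  list(coef = out, freqs = bank@freqs, fs = fs, window = trim)
}

#' Wavelet reconstruction quality (R-squared grid)
#'
#' Reconstructs each trial as the sum over frequencies of the real part of the
#' wavelet-filtered signals, then, per wavelet band, band-pass filters both the
#' original and the reconstruction within the wavelet's spectral bandwidth and
#' regresses original on reconstruction in sliding windows (500 ms, 25 ms
#' step). Returns the R-squared per (frequency x window), averaged over
#' trials; zero-variance windows yield `NA`.
#'
#' @inheritParams waveletTransform
#' @param winLen,step sliding-window length and step in seconds.
#' @return A list with `r2` (freq x window matrix), `freqs`, `centers`
#'   (window centres, seconds) and `overall` (median R-squared).
#' @export
reconstructionR2 <- function(epochs, bank, trim = NULL, winLen = 0.5,
                             step = 0.025, fs = NULL, window = NULL) {
  if (is(epochs, "LFPEpochs")) {
    x <- epochs@samples; fs <- epochs@fs; window <- epochs@window
  } else {
    x <- epochs
    if (is.null(window)) window <- c(0, ncol(x) / fs)
  }
  if (is.null(trim)) trim <- window
  wt <- waveletTransform(x, bank, trim = trim, fs = fs, window = window)
  ntr <- dim(wt$coef)[1]; nf <- dim(wt$coef)[2]; nt <- dim(wt$coef)[3]
  recon <- apply(Re(wt$coef), c(1, 3), sum)
  i0 <- round((trim[1] - window[1]) * fs) + 1L
  orig <- x[, i0:(i0 + nt - 1L), drop = FALSE]
  wlen <- round(winLen * fs)
  starts <- seq(1L, nt - wlen + 1L, by = max(1L, round(step * fs)))
  r2 <- matrix(NA_real_, nf, length(starts))
  for (f in seq_len(nf)) {
    bw <- bank@freqs[f] / bank@cycles[f] * 2   # ~2 sd spectral bandwidth
    bandf <- c(max(0.5, bank@freqs[f] - bw), min(fs / 2 - 1, bank@freqs[f] + bw))
    ofilt <- zeroPhaseFilter(orig, fs, "pass", bandf)
    rfilt <- zeroPhaseFilter(recon, fs, "pass", bandf)
    for (w in seq_along(starts)) {
      idx <- starts[w]:(starts[w] + wlen - 1L)
      vals <- vapply(seq_len(ntr), function(tr) {
        a <- ofilt[tr, idx]; b <- rfilt[tr, idx]
        if (!all(is.finite(a)) || sd(a) == 0 || sd(b) == 0) return(NA_real_)
        summary(lm(a ~ b))$r.squared
      }, numeric(1))
      r2[f, w] <- mean(vals, na.rm = TRUE)
    }
  }
  centers <- trim[1] + (starts - 1L) / fs + winLen / 2
  list(r2 = r2, freqs = bank@freqs, centers = centers,
       overall = median(r2, na.rm = TRUE))
}
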