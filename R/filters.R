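# Zero-phase FIR filtering.
#
# All filters are symmetric (Type-I linear-phase) Hamming-windowed-sinc FIR
# kernels applied by centred convolution with reflection padding, which is
# exactly zero-phase. Transition width follows
# tw = min(max(0.25 * f_edge, 2 Hz), f_edge) with f_edge the lower band edge,
# except band-stops, where tw is additionally capped at the stop-band width so
# narrow line-noise notches stay narrow.

.firOrder <- function(tw, fs) {
  # Hamming window: ~3.3 / normalized transition width, rounded up to even
  m <- ceiling(3.3 * fs / tw)
  if (m %% 2L == 1L) m <- m + 1L
  m
}

.hammingSinc <- function(fc, fs, m) {
  # low-pass windowed sinc, cutoff fc (-6 dB), length m + 1 (odd)
  n <- seq(-m / 2, m / 2)
  h <- 2 * fc / fs * sinc_(2 * fc / fs * n)
  w <- 0.54 + 0.46 * cos(2 * pi * n / (m + 1))
  h <- h * w
  h / sum(h)
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Design a zero-phase FIR kernel
#'
#' @param type `"low"`, `"high"`, `"pass"` or `"stop"`.
#' @param band cutoff (scalar for low/high) or `c(f1, f2)` band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param maxLength optional cap on kernel length (forced odd); used when the
#'   data segments are short.
#' @return Numeric symmetric kernel of odd length.
#' @export
firKernel <- function(type = c("low", "high", "pass", "stop"), band, fs,
                      maxLength = NULL) {
  type <- match.arg(type)
  fe <- min(band)
  tw <- min(max(0.25 * fe, 2), fe)
  if (type == "stop") tw <- min(tw, diff(range(band)))
  m <- .firOrder(tw, fs)
  if (!is.null(maxLength)) {
    L <- maxLength - (1 - maxLength %% 2L)  # odd
    m <- min(m, L - 1L)
  }
  delta <- function(m) { d <- numeric(m + 1L); d[m / 2 + 1L] <- 1; d }
  switch(type,
    low = .hammingSinc(band[1], fs, m),
    high = delta(m) - .hammingSinc(band[1], fs, m),
    pass = .hammingSinc(band[2], fs, m) - .hammingSinc(band[1], fs, m),
    stop = delta(m) - (.hammingSinc(band[2], fs, m) -
                       .hammingSinc(band[1], fs, m))
  )
}

# Centred convolution of each row of x with a kernel, reflection padding.
# Exactly zero-phase for symmetric kernels; also used with complex (Morlet)
# kernels. x may be a vector or a trials x time matrix.
convSame <- function(x, kernel) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1L)
  n <- ncol(x)
  L <- length(kernel)
  p <- (L - 1L) %/% 2L
  if (p >= n)
    stop("kernel too long for the data segment (", L, " taps vs ", n,
         " samples)")
  idx <- c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  xp <- x[, idx, drop = FALSE]
  npad <- n + 2L * p
  nfft <- stats::nextn(npad + L - 1L, c(2L, 3L, 5L))
  K <- fft(c(kernel, rep(0, nfft - L)))
  X <- mvfft(rbind(t(xp), matrix(0, nfft - npad, nrow(x))))
  yfull <- mvfft(X * K, inverse = TRUE) / nfft
  # sample t of the original maps to full-conv index t + p + (L-1)/2
  out <- t(yfull[(2L * p + 1L):(2L * p + n), , drop = FALSE])
  if (!is.complex(kernel)) out <- Re(out)
  if (vec) out <- drop(out)
  out
}

#' Zero-phase band-pass/low-pass/band-stop filtering
#'
#' @param x numeric vector or trials x time matrix.
#' @param fs sampling rate in Hz.
#' @inheritParams firKernel
#' @return Filtered data, same shape as `x`.
#' @export
zeroPhaseFilter <- function(x, fs, type, band, maxLength = NULL) {
  n <- if (is.null(dim(x))) length(x) else ncol(x)
  k <- firKernel(type, band, fs, maxLength = min(maxLength, 2L * (n %/% 2L) - 1L))
  convSame(x, k)
}

#' Analytic signal via the Hilbert transform
#'
#' Frequency-domain construction of the analytic signal `x + i * H(x)` of each
#' row, from which instantaneous phase (`Arg`, radians, 0 at a cosine peak)
#' and amplitude (`Mod`) follow.
#'
#' @param x numeric vector or trials x time matrix (rows are trials).
#' @return Complex data of the same shape.
#' @export
analyticSignal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1L)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  X <- mvfft(t(x))
  out <- t(mvfft(X * h, inverse = TRUE) / n)
  if (vec) out <- drop(out)
  out
}
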