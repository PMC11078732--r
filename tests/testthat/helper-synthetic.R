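# Shared fixtures, built in code. The small session keeps per-file runtime
# down; tests that need the full 140-trial study conditions build their own.

smallConfig <- function(seed = 101L, ...) {
  syntheticConfig(nTrials = 16L, loadSplit = c(8L, 8L),
                  unitSpecs = defaultUnitSpecs(1L, 1L, 1L, 1L),
                  seed = seed, ...)
}

# memoised small session reused across tests in a file
.sessCache <- new.env()
smallSession <- function(seed = 101L) {
  key <- as.character(seed)
  if (is.null(.sessCache[[key]]))
    .sessCache[[key]] <- simulateSession(smallConfig(seed))
  .sessCache[[key]]
}

# independent brute-force MI oracle: direct phase-binned amplitude histogram
miOracle <- function(phase, amplitude, nBins = 18L) {
  ph <- (phase + pi) %% (2 * pi)
  idx <- pmin(floor(ph / (2 * pi) * nBins) + 1L, nBins)
  means <- vapply(seq_len(nBins), function(b) mean(amplitude[idx == b]),
                  numeric(1))
  p <- means / sum(means)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  (log(nBins) - h) / log(nBins)
}

# von Mises sampler by rejection from a uniform proposal
rvonmises <- function(n, kappa, mu = 0) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, -pi, pi)
    keep <- runif(2 * n) < exp(kappa * (cos(x) - 1))
    out <- c(out, x[keep])
  }
  ((out[seq_len(n)] + mu + pi) %% (2 * pi)) - pi
}
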