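test_that("spike phases are read off the nearest LFP sample", {
  fs <- 400
  t <- seq(-0.5, 3.0 - 1 / fs, by = 1 / fs)
  ep <- matrix(cos(2 * pi * 5 * t), 2, length(t), byrow = TRUE)
  ph <- hilbertPhaseAmp(ep, c(3, 7), fs = fs, window = c(-0.5, 3.0))$phase
  # spikes exactly at theta peaks: t = k / 5
  peaks <- seq(0.2, 2.4, by = 0.2)
  sp <- spikePhases(list(peaks, peaks), ph, fs)
  expect_identical(nrow(sp$phases), 2L * length(peaks))
  expect_lt(max(abs(sp$phases)), 0.15)
  # off-grid spike matches brute-force nearest-sample search
  off <- 1.2341
  sp2 <- spikePhases(list(off, numeric(0)), ph, fs)
  grid <- seq(0, 2.5 - 1 / fs, by = 1 / fs)
  expect_equal(sp2$phases[1, 1], ph[1, which.min(abs(grid - off))])
  # empty unit: empty result, no error
  sp3 <- spikePhases(list(numeric(0), numeric(0)), ph, fs)
  expect_identical(nrow(sp3$phases), 0L)
  # spikes outside the window are dropped and counted
  sp4 <- spikePhases(list(c(-0.2, 1, 2.7), numeric(0)), ph, fs)
  expect_identical(nrow(sp4$phases), 1L)
  expect_identical(sp4$nDropped, 2L)
})

test_that("MVL extremes and exact rotation invariance", {
  expect_equal(pacwm:::.mvl(rep(1.3, 500)), 1, tolerance = 1e-12)
  set.seed(14)
  ph <- runif(300, -pi, pi)
  r0 <- pacwm:::.mvl(ph)
  r1 <- pacwm:::.mvl(((ph + 2.1 + pi) %% (2 * pi)) - pi)
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("von Mises locking matches the Bessel-ratio closed form", {
  set.seed(15)
  ph <- rvonmises(4000, 2)
  mv <- mvlSubsampled(list(all = ph), minSpikes = 50, nRep = 5)
  expect_lt(abs(unname(mv$mvl[1, 1]) - besselI(2, 1) / besselI(2, 0)),
            0.03)
})

test_that("spike-count equalisation removes the MVL sample-size bias", {
  set.seed(16)
  # over replicate datasets, the 100-spike condition and the subsampled
  # 10000-spike condition share the same small-sample MVL bias
  diffs <- replicate(40, {
    few <- runif(100, -pi, pi)
    many <- runif(10000, -pi, pi)
    mv <- mvlSubsampled(list(few = few, many = many), minSpikes = 50,
                        nRep = 40)
    mv$mvl[1, 1] - mv$mvl[2, 1]
  })
  expect_lt(abs(mean(diffs)), 0.02)
  mv <- mvlSubsampled(list(few = runif(100, -pi, pi),
                           many = runif(10000, -pi, pi)), minSpikes = 50,
                      nRep = 5)
  expect_identical(mv$nSpikesUsed, 100L)
  # under-sampled conditions exclude the pair with a reason
  ex <- mvlSubsampled(list(a = runif(200, -pi, pi),
                           b = runif(20, -pi, pi)), minSpikes = 50)
  expect_true(ex$excluded)
  expect_match(ex$reason, "20 < 50")
})

test_that("jitter surrogates flag locked spikes and spare unlocked ones", {
  fs <- 400
  t <- seq(-0.5, 3.0 - 1 / fs, by = 1 / fs)
  ntr <- 10
  ep <- matrix(cos(2 * pi * 5 * t), ntr, length(t), byrow = TRUE)
  ph <- hilbertPhaseAmp(ep, c(3, 7), fs = fs, window = c(-0.5, 3.0))$phase
  set.seed(17)
  # locked spikes: von Mises around the peak, mapped to spike times
  locked <- lapply(seq_len(ntr), function(i) {
    k <- sample(0:11, 25, replace = TRUE)
    pmin(2.5 - 1e-4, pmax(0, k * 0.2 + rvonmises(25, 1) / (2 * pi * 5)))
  })
  spL <- spikePhases(locked, ph, fs)
  rawL <- pacwm:::.mvl(spL$phases)
  zL <- jitterZ(rawL, locked, ph, fs, nSurrogates = 60)
  expect_gt(zL$z, 3)
  unlocked <- lapply(seq_len(ntr), function(i) runif(25, 0, 2.5))
  spU <- spikePhases(unlocked, ph, fs)
  zU <- jitterZ(pacwm:::.mvl(spU$phases), unlocked, ph, fs, nSurrogates = 60)
  expect_lt(abs(zU$z), 3)
})

test_that("condition contrasts find injected clusters where they are", {
  set.seed(18)
  nPairs <- 14; nFreq <- 40
  thetaIdx <- 9:13
  zB <- matrix(rnorm(nPairs * nFreq), nPairs)
  zA <- zB + matrix(rnorm(nPairs * nFreq, 0, 0.3), nPairs)
  zA[, thetaIdx] <- zA[, thetaIdx] + 1.5
  freqs <- morletBank(400)@freqs
  res <- sfcContrast(zA, zB, freqs = freqs, nPerm = 1000)
  sig <- res$clusters[res$clusters$significant & res$clusters$sign > 0, ]
  expect_gte(nrow(sig), 1L)
  expect_true(any(sig$start <= min(thetaIdx) + 1 &
                  sig$end >= max(thetaIdx) - 1))
  # no significant cluster outside the injected range
  expect_false(any(sig$start > max(thetaIdx)))
  # Bonferroni option tightens the cluster alpha
  res2 <- sfcContrast(zA, zB, nPerm = 200, bonferroniN = 12)
  expect_equal(res2$alphaCluster, 0.025 / 12)
})

test_that("gamma-amplitude split isolates amplitude-gated locking", {
  set.seed(19)
  n <- 1200
  gamma <- rexp(n)
  hi <- gamma > median(gamma)
  pref <- rep(c(TRUE, FALSE), n / 2)
  # locking only when preferred AND high gamma
  ph <- ifelse(pref & hi, rvonmises(n, 3), runif(n, -pi, pi))
  res <- gammaAmplitudeSplitSfc(ph, gamma, factor(pref,
                                                  levels = c(TRUE, FALSE)),
                                minSpikes = 10, nRep = 50)
  expect_gt(res$high$diff[1], 0.3)
  expect_lt(abs(res$low$diff[1]), 0.15)
  # the split preserves the total spike count
  nHigh <- sum(hi); nLow <- sum(!hi)
  expect_identical(nHigh + nLow, as.integer(n))
})
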