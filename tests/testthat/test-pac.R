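test_that("the modulation index hits its entropy extremes", {
  set.seed(10)
  ph <- runif(20000, -pi, pi)
  # flat amplitude: maximal entropy, MI = 0
  expect_equal(modulationIndex(ph, rep(2.5, length(ph)))$mi, 0,
               tolerance = 1e-12)
  # all amplitude mass in one bin: zero entropy, MI = 1
  amp <- as.numeric(ph > -pi & ph < -pi + 2 * pi / 18)
  expect_equal(modulationIndex(ph, amp)$mi, 1, tolerance = 1e-12)
})

test_that("MI is exactly invariant to positive amplitude rescaling", {
  set.seed(11)
  ph <- runif(5000, -pi, pi)
  amp <- 1 + 0.5 * cos(ph) + abs(rnorm(5000, 0, 0.1))
  expect_identical(modulationIndex(ph, amp)$mi,
                   modulationIndex(ph, amp * 1234.5)$mi)
})

test_that("empty phase bins raise an error naming the bin", {
  ph <- runif(1000, 0, 1)   # only positive phases: low bins empty
  expect_error(modulationIndex(ph, rep(1, 1000)), "empty phase bin")
})

test_that("preferred phase points at the amplitude peak", {
  ph <- seq(-pi, pi, length.out = 40000)
  amp <- 1 + 0.8 * cos(ph - 1.0)
  mi <- modulationIndex(ph, amp)
  expect_lt(abs(mi$preferredPhase - 1.0), 2 * pi / 18)
})

test_that("surrogate machinery: fast path, derangements, invariances", {
  set.seed(12)
  ntr <- 14; nt <- 500
  ph <- matrix(runif(ntr * nt, -pi, pi), ntr)
  am <- matrix(1 + 0.4 * cos(as.vector(t(ph))) + abs(rnorm(ntr * nt, 0, .2)),
               ntr, byrow = TRUE)
  res <- surrogateZ(ph, am, nSurrogates = 50)
  # identity pairing of the fast path equals the concatenated-stream MI
  expect_equal(res$rawMI,
               modulationIndex(as.vector(t(ph)), as.vector(t(am)))$mi,
               tolerance = 1e-12)
  # permuting the trial order of both streams identically leaves raw MI fixed
  p <- sample(ntr)
  res2 <- surrogateZ(ph[p, ], am[p, ], nSurrogates = 50)
  expect_equal(res2$rawMI, res$rawMI, tolerance = 1e-12)
  # derangements never pair a trial with itself
  for (i in 1:20) expect_true(all(pacwm:::.derangement(12) != 1:12))
  expect_error(surrogateZ(ph[1:5, ], am[1:5, ]), "at least 10 trials")
})

test_that("injected coupling produces a comodulogram hotspot at the right cell", {
  cfg <- smallConfig(21L, pacDepth = c(load1 = 0.8, load3 = 0.8),
                     pacTrialSd = 0)
  set.seed(cfg$seed)
  tr <- simulateTrialTable(cfg)
  lf <- simulateLfp(cfg, tr)
  cm <- computeComodulogram(lf$epochs, nSurrogates = 40)
  expect_identical(dim(cm@zMI), c(7L, 25L))
  expect_identical(cm@phaseCenters, seq(2, 14, 2))
  expect_identical(cm@ampCenters, seq(30, 150, 5))
  # hottest phase row should be the theta row nearest the injected 5 Hz
  hot <- which(cm@zMI == max(cm@zMI), arr.ind = TRUE)
  expect_true(cm@phaseCenters[hot[1, 1]] %in% c(4, 6))
  expect_true(cm@ampCenters[hot[1, 2]] >= 70 - 10)
  sel <- selectPacChannels(list(ch1 = cm))
  expect_true(sel$sig_highGamma)
  expect_equal(attr(sel, "threshold"), qnorm(0.95))
})

test_that("load contrast recovers the injected direction and applies FDR", {
  set.seed(13)
  # per-channel z values: load 1 stronger than load 3 in one area
  z1 <- rnorm(12, 5, 1); z3 <- z1 - rnorm(12, 1.5, 0.3)
  lc <- loadContrast(z1, z3, areas = rep("hippocampus", 12), nPerm = 2000)
  expect_lt(lc$meanDiff[1], 0)          # load3 - load1 negative
  expect_true(lc$significant[1])
  expect_true("p_fdr" %in% names(lc))
  expect_error(loadContrast(1, 2), "at least 2")
})

test_that("single-trial PAC tracks the injected per-trial depth", {
  cfg <- syntheticConfig(seed = 22L, nTrials = 20L, loadSplit = c(10L, 10L),
                         pacTrialSd = 0.6)
  set.seed(cfg$seed)
  tr <- simulateTrialTable(cfg)
  lf <- simulateLfp(cfg, tr)
  mi <- singleTrialPac(lf$epochs)
  expect_length(mi, 20L)
  expect_gt(cor(mi, lf$truth$kappaTrial, method = "spearman"), 0.4)
})

test_that("cycle asymmetries are 0.5 for a sinusoid and flip on reversal", {
  fs <- 400
  t <- seq(0, 2.5 - 1 / fs, by = 1 / fs)
  sine <- matrix(sin(2 * pi * 5 * t), 1)
  ca <- cycleAsymmetry(sine, band = NULL, fs = fs)
  expect_lt(abs(ca$pt - 0.5), 0.02)
  expect_lt(abs(ca$rd - 0.5), 0.02)
  # smooth sawtooth: slow rise, fast decay -> rd > 0.5
  saw <- 0
  for (k in 1:8) saw <- saw + (-1)^(k + 1) / k * sin(2 * pi * 5 * k * t)
  ca2 <- cycleAsymmetry(matrix(saw, 1), band = NULL, fs = fs)
  expect_gt(ca2$rd, 0.55)
  ca3 <- cycleAsymmetry(matrix(rev(saw), 1), band = NULL, fs = fs)
  expect_equal(ca2$rd + ca3$rd, 1, tolerance = 0.05)
  # too few cycles -> NA
  short <- matrix(sin(2 * pi * 5 * t[1:200]), 1)
  expect_true(is.na(cycleAsymmetry(short, band = NULL, fs = fs,
                                   minCycles = 5L)$pt))
})

test_that("nesting is detected for peak-locked gamma bursts and not for pure theta", {
  fs <- 400
  w <- c(-0.5, 3.0)
  t <- seq(w[1], w[2] - 1 / fs, by = 1 / fs)
  nTrials <- 12
  mk <- function(gamma) {
    m <- matrix(0, nTrials, length(t))
    for (i in seq_len(nTrials)) {
      th <- 2 * pi * 5 * t
      x <- 10 * cos(th)
      if (gamma) x <- x + 3 * exp(2 * (cos(th) - 1)) * cos(2 * pi * 80 * t)
      m[i, ] <- x
    }
    m
  }
  build <- function(gamma) {
    raw <- LFPEpochs("c", "hippocampus", fs, mk(gamma), w)
    ph <- hilbertPhaseAmp(raw, c(3, 7))$phase
    am <- hilbertPhaseAmp(raw, c(70, 140))$amplitude
    pref <- pacwm:::.phaseBin(0, 18L)
    detectNesting(raw, ph, am, pref)
  }
  yes <- build(TRUE)
  no <- build(FALSE)
  expect_true(yes$nested)
  expect_true(yes$reliable)
  expect_false(no$nested)
})
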