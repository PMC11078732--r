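test_that("spike transients are replaced by the joining line, rest untouched", {
  fs <- 8000
  trace <- sin(2 * pi * 3 * (0:7999) / fs)
  spk <- 0.5
  pulse <- trace
  i1 <- round((spk) * fs); pulse[i1:(i1 + 7)] <- pulse[i1:(i1 + 7)] + 50
  out <- removeSpikeTransients(pulse, fs, spk)
  win <- (floor((spk - 0.001) * fs) + 1):(ceiling((spk + 0.002) * fs) + 1)
  expect_true(all(abs(out[win]) < 1.1))            # pulse removed
  expect_identical(out[-win], pulse[-win])         # all else bit-identical
  d2 <- diff(diff(out[win]))
  expect_true(all(abs(d2) < 1e-9))                 # residual is a straight line
  # no spikes: identity
  expect_identical(removeSpikeTransients(trace, fs, numeric()), trace)
})

test_that("overlapping spike windows merge into one interpolation", {
  fs <- 8000
  set.seed(3)
  trace <- rnorm(4000)
  spikes <- c(0.2, 0.201)  # 1 ms apart: windows overlap
  out <- removeSpikeTransients(trace, fs, spikes)
  # oracle: naive per-sample marking, then interpolate over the merged run
  mark <- rep(FALSE, length(trace))
  for (s in spikes) {
    a <- floor((s - 0.001) * fs) + 1L
    b <- ceiling((s + 0.002) * fs) + 1L
    mark[a:b] <- TRUE
  }
  r <- rle(mark); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  oracle <- trace
  for (k in which(r$values)) {
    lo <- starts[k] - 1L; hi <- ends[k] + 1L
    w <- seq_len(ends[k] - starts[k] + 1L) / (hi - lo)
    oracle[starts[k]:ends[k]] <- trace[lo] * (1 - w) + trace[hi] * w
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("line noise is notched and the passband preserved", {
  fs <- 8000
  t <- (0:(fs * 10 - 1)) / fs
  y60 <- filterDownsample(sin(2 * pi * 60 * t), fs)$trace
  y10 <- filterDownsample(sin(2 * pi * 10 * t), fs)$trace
  mid <- 1200:2800   # 3-7 s: clear of filter edges
  expect_lt(20 * log10(sd(y60[mid]) / sd(sin(2 * pi * 60 * t))), -40)
  expect_lt(abs(sd(y10[mid]) * sqrt(2) - 1), 0.01)  # amplitude within 1%
  # zero phase: peak positions of the 10 Hz tone unmoved
  x10 <- sin(2 * pi * 10 * (mid - 1) / 400)
  expect_gt(cor(x10, y10[mid]), 0.9999)
  expect_error(filterDownsample(rnorm(1000), 300), "at least")
})

test_that("preprocessing is near-idempotent on clean 400 Hz data", {
  set.seed(4)
  # clean = already filtered, notched and band-limited below the low-pass
  # roll-off; a second pass must change it by well under 1% RMS
  t <- (0:(400 * 6 - 1)) / 400
  x <- rowSums(sapply(c(7, 23, 41, 83, 101, 137), function(f)
    sin(2 * pi * f * t + f)))
  y <- filterDownsample(x, 400)$trace
  mid <- 800:1600
  expect_lt(sqrt(mean((y[mid] - x[mid])^2)) / sd(x[mid]), 0.01)
})

test_that("artifact screening matches a direct application of the rules", {
  set.seed(5)
  ep <- matrix(rnorm(60 * 1400), 60)
  ep[9, 200] <- 40
  res <- detectArtifactTrials(ep)
  # oracle: literal rule evaluation
  z <- (ep - mean(ep)) / sd(as.vector(ep))
  z <- pmin(pmax(z, -6), 6)
  z2 <- (z - mean(z)) / sd(as.vector(z))
  ampBad <- apply(abs(z2) > 4, 1L, any)
  d <- z[, 5:1400] - z[, 1:1396]
  jumpBad <- apply(abs((d - mean(d)) / sd(as.vector(d))) > 10, 1L, any)
  expect_identical(res$valid, !(ampBad | jumpBad))
  expect_false(res$valid[9])
})

test_that("a step passing the amplitude rule is caught by the jump rule", {
  set.seed(6)
  # smooth low-frequency signal: lag-4 differences are tiny, so a modest step
  # is a >10 SD jump while staying under 4 SD in amplitude
  t <- seq(0, 3.5, length.out = 1400)
  ep <- t(replicate(40, sin(2 * pi * 1.5 * t + runif(1, 0, 2 * pi))))
  ep <- ep + rnorm(length(ep), 0, 0.01)
  ep[12, 700:1400] <- ep[12, 700:1400] + 1.0
  res <- detectArtifactTrials(ep)
  expect_false(res$valid[12])
  expect_gte(res$report$jump_rejected, 1L)
})

test_that("the artifact mask is invariant to affine rescaling", {
  set.seed(7)
  ep <- matrix(rnorm(40 * 1400), 40)
  ep[3, 100] <- 30
  a <- detectArtifactTrials(ep)
  b <- detectArtifactTrials(ep * 12.7 - 300)
  expect_identical(a$valid, b$valid)
  expect_warning(r <- detectArtifactTrials(matrix(1, 10, 100)), "zero-variance")
  expect_true(all(r$valid))
})
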