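test_that("sliding counts produce 101 bins with the right rates", {
  set.seed(23)
  st <- lapply(1:20, function(i) sort(runif(rpois(1, 25), -0.2, 2.7)))
  m <- slidingCounts(st)
  expect_identical(ncol(m), 101L)
  # constant-rate unit: mean count per 200 ms window ~ rate * 0.2
  rate <- 40
  st2 <- lapply(1:30, function(i) sort(runif(rpois(1, rate * 2.9), -0.2, 2.7)))
  m2 <- slidingCounts(st2)
  expect_equal(mean(m2), rate / 2.9 * 2.9 * 0.2, tolerance = 0.1)
  # empty unit: zero matrix
  expect_true(all(slidingCounts(list(numeric(0), numeric(0))) == 0L))
})

test_that("within-category shuffling preserves per-unit count multisets", {
  set.seed(24)
  labels <- rep(1:5, each = 8)
  counts <- lapply(1:6, function(u) matrix(rpois(40 * 101, 3), 40))
  sh <- removeNoiseCorrelations(counts, labels)
  for (u in 1:6) for (lv in 1:5) {
    a <- counts[[u]][labels == lv, , drop = FALSE]
    b <- sh[[u]][labels == lv, , drop = FALSE]
    # exact multiset equality of rows within each category
    expect_identical(sort(apply(a, 1, paste, collapse = ",")),
                     sort(apply(b, 1, paste, collapse = ",")))
    expect_identical(colSums(a), colSums(b))   # category means unchanged
  }
})

test_that("shuffling drives shared-gain correlations into the null band", {
  set.seed(25)
  nTr <- 60; nU <- 20
  labels <- rep(1:5, each = 12)
  shared <- rnorm(nTr, 0, 2)
  X <- sapply(1:nU, function(u) rpois(nTr, exp(1.5 + 0.4 * shared)))
  pairR <- function(M) {
    cc <- cor(M)
    mean(cc[upper.tri(cc)])
  }
  rBefore <- pairR(X)
  expect_gt(rBefore, 0.3)
  rAfter <- replicate(20, pairR(removeNoiseCorrelations(X, labels)))
  # the residual after within-category shuffling is the finite-sample
  # category-mean component; it must be a small fraction of the original
  expect_lt(abs(mean(rAfter)), rBefore / 5)
})

test_that("noise correlation inference separates coupled from independent pairs", {
  set.seed(26)
  nTr <- 50; nBins <- 101
  cond <- rep(1:2, each = 25)
  slow <- matrix(rnorm(nTr * nBins), nTr)
  for (i in seq_len(nTr)) slow[i, ] <- filter(slow[i, ], rep(1 / 8, 8),
                                              circular = TRUE)
  mk <- function(coupled) {
    a <- matrix(rpois(nTr * nBins, exp(1 + 2 * slow * coupled)), nTr)
    b <- matrix(rpois(nTr * nBins, exp(1 + 2 * slow * coupled)), nTr)
    list(a = a, b = b)
  }
  cp <- mk(1)
  r1 <- noiseCorrelation(cp$a, cp$b, conditions = cond, nShuffle = 100)
  expect_gt(r1$r, quantile(r1$null, 0.99))
  ind <- mk(0)
  r0 <- noiseCorrelation(ind$a, ind$b, conditions = cond, nShuffle = 100)
  expect_true(r0$r > r0$band95[1] - 0.02 && r0$r < r0$band95[2] + 0.02)
  expect_error(noiseCorrelation(cp$a, cp$b, sameChannel = TRUE),
               "same channel")
})

test_that("greedy decoding is perfect for a noiseless tuned unit and near
           chance without signal", {
  set.seed(27)
  labels <- rep(1:5, each = 20)
  X <- cbind(as.numeric(labels) + rnorm(100, 0, 0.01), rnorm(100))
  g <- greedyDecoding(X, labels, nRep = 15)
  expect_gt(g$accIntact[1], 0.95)
  expect_identical(g$order[1], 1L)
  expect_identical(g$chance, 0.2)
  # curve does not collapse when the noise unit is added
  expect_gt(g$accIntact[2], 0.9)
})

test_that("correlated untuned partners enhance decoding via noise cancellation", {
  set.seed(28)
  g <- simulateTwoNeuronGeometry(150, offset = 2, sharedSd = 1.5)
  accI <- pacwm:::.svmAccuracy(g$rates, g$labels, nRep = 40)
  accR <- pacwm:::.svmAccuracy(g$rates, g$labels, nRep = 40,
                               removeCorr = TRUE)
  expect_gt(accI, accR)
})

test_that("ablation of informative units lowers maximal accuracy", {
  set.seed(29)
  labels <- rep(1:5, each = 12)
  tuned <- sapply(1:2, function(u) as.numeric(labels == u) * 3 +
                                   rnorm(60, 0, 0.5))
  noise <- matrix(rnorm(60 * 3), 60)
  X <- cbind(tuned, noise)
  ab <- pacAblation(X, labels, pacUnits = 1:2, nRep = 10, nDraws = 5)
  expect_gt(ab$maxAccFull, ab$maxAccNoPac)
  expect_gt(ab$maxAccRandomRemoval, ab$maxAccNoPac)
})

test_that("the angle estimator matches constructed geometries", {
  set.seed(30)
  n <- 400
  labels <- factor(rep(c("A", "B"), each = n / 2))
  # signal along e1, noise overwhelmingly along e2: angle ~ 90 degrees
  X <- cbind(2 * (labels == "B") + rnorm(n, 0, 0.05), rnorm(n, 0, 3))
  geo <- signalNoiseGeometry(X, labels, nRep = 15)
  expect_gt(geo$angleIntact, 85)
  # enhancing regime: intact angle larger, projection s.d. smaller
  g <- simulateTwoNeuronGeometry(200, offset = 2, sharedSd = 1.5)
  ge <- signalNoiseGeometry(g$rates, g$labels, nRep = 15)
  expect_gt(ge$angleIntact, ge$angleRemoved)
  expect_gt(ge$projSdRemoved, ge$projSdIntact)
})

test_that("fast/slow RT splits recover a coupling of correlations to behaviour", {
  set.seed(31)
  nTr <- 80; nBins <- 101
  load <- rep(c(1, 3), each = nTr / 2)
  strength <- runif(nTr)          # per-trial co-fluctuation strength
  rt <- 1.5 - 0.8 * strength + 0.3 * (load == 3) + rnorm(nTr, 0, 0.1)
  mkPair <- function() {
    a <- b <- matrix(0, nTr, nBins)
    for (i in seq_len(nTr)) {
      common <- filter(rnorm(nBins), rep(1 / 6, 6), circular = TRUE)
      a[i, ] <- rpois(nBins, exp(1 + 1.5 * strength[i] * common))
      b[i, ] <- rpois(nBins, exp(1 + 1.5 * strength[i] * common))
    }
    list(a = a, b = b)
  }
  pairs_ <- replicate(6, mkPair(), simplify = FALSE)
  res <- rtSplitCorrelations(pairs_, rt, load, nPerm = 500)
  expect_gt(mean(res$perPair$diff), 0)
  expect_lt(res$p, 0.05)
  # RT independent of the co-fluctuations: contrast centred on zero
  rt0 <- 1.5 + 0.3 * (load == 3) + rnorm(nTr, 0, 0.1)
  res0 <- rtSplitCorrelations(pairs_, rt0, load, nPerm = 500)
  expect_gt(res0$p, 0.05)
})
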