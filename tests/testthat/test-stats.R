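test_that("permutation t-tests match exact enumeration at small n", {
  set.seed(32)
  d <- c(0.3, 1.2, -0.4, 0.8, 0.2, 1.5, -0.1, 0.9)
  # exact null: all 2^8 sign flips
  tObs <- mean(d) / (sd(d) / sqrt(8))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  tAll <- apply(signs, 1L, function(s) {
    x <- d * s
    mean(x) / (sd(x) / sqrt(8))
  })
  pExact <- mean(abs(tAll) >= abs(tObs) - 1e-12)
  res <- permTTest(d, nPerm = 20000)
  expect_equal(res$t, tObs, tolerance = 1e-12)
  expect_lt(abs(res$p - pExact), 0.02)
})

test_that("degenerate and powered cases of the permutation t-test", {
  x <- rnorm(20)
  expect_warning(r <- permTTest(x, x, paired = TRUE, nPerm = 200), "constant")
  expect_identical(r$p, 1)
  set.seed(33)
  a <- rnorm(50, 2, 1); b <- rnorm(50, 0, 1)
  expect_lt(permTTest(a, b, nPerm = 2000)$p, 0.01)
  # one-sided direction
  expect_lt(permTTest(a, b, nPerm = 2000, sided = "greater")$p, 0.01)
  expect_gt(permTTest(a, b, nPerm = 2000, sided = "less")$p, 0.9)
  # p respects the +1 bound
  expect_gte(permTTest(a, b, nPerm = 500)$p, 1 / 501)
})

test_that("permutation ANOVA flags a shifted group and respects exchangeability", {
  set.seed(34)
  g <- rep(1:5, each = 15)
  v <- rnorm(75)
  v[g == 3] <- v[g == 3] + 1.5
  expect_lt(permAnova(v, g, nPerm = 1000)$p, 0.05)
  # relabelling the groups leaves F identical
  f1 <- permAnova(v, g, nPerm = 10)$F
  f2 <- permAnova(v, c(3, 4, 5, 1, 2)[g], nPerm = 10)$F
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_error(permAnova(1:3, c(1, 1, 2)), "2 observations")
})

test_that("cluster permutation finds injected bands and nothing else", {
  set.seed(35)
  n <- 12; nf <- 30
  d <- matrix(rnorm(n * nf, 0, 1), n)
  d[, 10:12] <- d[, 10:12] + 1.8
  res <- clusterPermFreq(d, nPerm = 1000)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1L)
  expect_true(any(sig$start <= 10 & sig$end >= 12))
  # global sign flip mirrors the clusters (two-sided use)
  resN <- clusterPermFreq(-d, nPerm = 1000)
  sigN <- resN$clusters[resN$clusters$significant, ]
  expect_identical(sig$start, sigN$start)
  expect_identical(sig$end, sigN$end)
  expect_identical(sig$sign, -sigN$sign)
  # pure noise: family-wise error controlled (spot check)
  d0 <- matrix(rnorm(n * nf), n)
  res0 <- clusterPermFreq(d0, nPerm = 500)
  expect_true(nrow(res0$clusters) == 0L ||
              all(res0$clusters$p > 1 / 501))
  expect_error(clusterPermFreq(d[1:3, ]), "at least 5")
})

test_that("single-frequency cluster test degenerates to the paired t-test", {
  set.seed(36)
  d <- matrix(rnorm(15, 0.8, 1), ncol = 1)
  cl <- clusterPermFreq(d, nPerm = 4000, alphaCluster = 0.025)
  tt <- permTTest(d[, 1], nPerm = 4000)
  if (nrow(cl$clusters)) {
    # one-sided cluster p vs two-sided t-test p: factor ~2
    expect_lt(abs(2 * cl$clusters$p[1] - tt$p), 0.05)
  } else {
    expect_gt(tt$p, 0.02)
  }
})

test_that("FDR mask and Bonferroni helpers behave", {
  expect_true(all(fdrMask(rep(0.001, 8), 0.01)$mask))
  expect_identical(fdrMask(numeric(0))$mask, logical(0))
  expect_identical(fdrMask(0.03, 0.05)$mask, TRUE)   # single p: plain threshold
  set.seed(37)
  p0 <- runif(200)
  expect_lt(mean(fdrMask(p0, 0.05)$mask), 0.05)
  expect_equal(bonferroniAlpha(0.05, 12), 0.05 / 12)
})

test_that("the mixed-model contract recovers a trial-level slope", {
  set.seed(38)
  nCh <- 8; nTrial <- 40
  dat <- do.call(rbind, lapply(seq_len(nCh), function(ch) {
    pac <- rnorm(nTrial)
    load <- sample(c(1, 3), nTrial, replace = TRUE)
    data.frame(channel = ch, pac = pac, load = factor(load),
               rt = 1.2 + rnorm(1, 0, 0.2) - 0.3 * pac +
                 0.2 * (load == 3) + rnorm(nTrial, 0, 0.3))
  }))
  fit <- fitMixedGlm(rt ~ pac + load + (1 | channel), dat)
  co <- fit$coefficients
  slope <- co[co$term == "pac", ]
  expect_lt(abs(slope$estimate - (-0.3)), 3 * slope$se)
  expect_lt(slope$p, 0.001)
  expect_false(fit$overdispersed)
})
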