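test_that("category neurons are recovered with the right preference", {
  sim <- smallSession(41L)
  cs <- selectCategoryNeurons(sim$session, nPerm = 300, nNull = 0)
  gt <- sim$truth$units
  tuned <- cs$tuning[gt$tuned, ]
  expect_true(all(tuned$selected))
  expect_identical(tuned$preferred_category,
                   gt$preferredCategory[gt$tuned])
  # untuned units are mostly not selected (allow one false positive)
  expect_lte(sum(cs$tuning$selected[!gt$tuned]), 1L)
})

test_that("the area-level null keeps homogeneous populations non-significant", {
  cfg <- syntheticConfig(nTrials = 24L, loadSplit = c(12L, 12L),
                         unitSpecs = defaultUnitSpecs(0L, 0L, 0L, 3L),
                         seed = 42L)
  sim <- simulateSession(cfg)
  cs <- selectCategoryNeurons(sim$session, nPerm = 200, nNull = 40)
  expect_false(any(cs$areaNull$significant))
})

test_that("the 20-bin design is complete and occupancy-proportional", {
  fs <- 400
  nt <- 1000; ntr <- 12
  set.seed(20)
  # non-uniform phase distribution, so bin occupancies differ strongly
  th <- matrix(rvonmises(ntr * nt, 1), ntr)
  ga <- matrix(rnorm(ntr * nt), ntr)
  # fixed-rate unit: one spike every 25 ms samples time (hence occupancy)
  st <- lapply(seq_len(ntr), function(i) seq(0.01, 2.49, by = 0.025))
  des <- buildPhaseGammaDesign(st, th, ga, rep(TRUE, ntr), fs)
  expect_identical(nrow(des), 20L)
  expect_identical(sort(unique(des$gamma)), c(0L, 1L))
  # median split halves the samples (up to ties)
  expect_lt(abs(sum(des$occupancy[des$gamma == 1]) -
                sum(des$occupancy[des$gamma == 0])), 2)
  # spike count proportional to occupancy for phase-blind firing
  expect_gt(cor(des$count, des$occupancy), 0.9)
  expect_identical(sum(des$count), 1200L)
})

test_that("likelihood ratios are non-negative and the interaction is found", {
  set.seed(21)
  centers <- rep(-pi + (1:10 - 0.5) * 2 * pi / 10, 2)
  gamma <- rep(c(0, 1), each = 10)
  occ <- rep(500L, 20)
  lam <- 50 * exp(0.3 * cos(centers) + (1.2 * cos(centers) + 0.6) * gamma)
  des <- data.frame(phaseBin = rep(1:10, 2), phaseCenter = centers,
                    gamma = gamma, count = rpois(20, lam),
                    occupancy = occ, exposure = occ / 400)
  fit <- fitPacModels(des)
  expect_gte(fit$lr[["lr12"]], 0)
  expect_gte(fit$lr[["lr13"]], 0)
  expect_lt(fit$p[["p12"]], 0.01)
  expect_lt(fit$p[["p13"]], 0.01)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
  # no-interaction data: p12 not systematically small
  des0 <- des
  des0$count <- rpois(20, 50 * exp(0.3 * cos(centers) + 0.6 * gamma))
  fit0 <- fitPacModels(des0)
  expect_gt(fit0$p[["p12"]], 0.001)
})

test_that("rotating theta by a whole bin leaves the LR tests unchanged", {
  fs <- 400
  nt <- 1000; ntr <- 12
  set.seed(22)
  th <- matrix(runif(ntr * nt, -pi, pi), ntr)
  ga <- matrix(rnorm(ntr * nt), ntr)
  st <- lapply(seq_len(ntr), function(i) sort(runif(60, 0, 2.5)))
  d1 <- buildPhaseGammaDesign(st, th, ga, rep(TRUE, ntr), fs)
  rot <- ((th + 2 * pi / 10 + pi) %% (2 * pi)) - pi
  d2 <- buildPhaseGammaDesign(st, rot, ga, rep(TRUE, ntr), fs)
  f1 <- fitPacModels(d1); f2 <- fitPacModels(d2)
  expect_equal(unname(f1$p), unname(f2$p), tolerance = 1e-6)
  expect_equal(f1$deviance[["m1"]], f2$deviance[["m1"]], tolerance = 1e-6)
})

test_that("PAC-neuron selection separates interacting units from the rest", {
  sim <- smallSession(43L)
  res <- selectPacNeurons(sim$session)
  gt <- sim$truth$units
  expect_identical(names(res$selection), c("unit_id", "region", "selected",
                                           "chosen_channel"))
  # the non-interacting units must not be selected (model-3 guard included)
  expect_false(any(res$selection$selected[!gt$pacInteracting]))
  expect_true(all(is.na(res$selection$chosen_channel[!res$selection$selected])))
})

test_that("the selection null preserves counts and yields sane p-values", {
  sim <- smallSession(43L)
  obs <- selectPacNeurons(sim$session)
  nul <- pacSelectionNull(sim$session, obs, nRep = 8)
  expect_true(all(nul$p >= 1 / 9 & nul$p <= 1))
})

test_that("the overlap test behaves at its corners", {
  units <- sprintf("u%03d", 1:200)
  expect_identical(overlapIndependenceTest(character(), units[1:50], 200)$p, 1)
  same <- units[1:40]
  expect_lt(overlapIndependenceTest(same, same, 200)$p, 1e-10)
  # overlap at the independence expectation sits mid-distribution
  pac <- units[1:80]; cat_ <- units[c(1:32, 100:147)]  # overlap 32 = 80*80/200
  p <- overlapIndependenceTest(pac, cat_, 200)$p
  expect_gt(p, 0.2); expect_lt(p, 0.8)
})
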