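# Noise correlations, greedy ensemble decoding and response geometry.

#' Sliding spike counts over the maintenance period
#'
#' Counts a unit's spikes in 200-ms windows slid in 25-ms steps, windows
#' centred at 0, 0.025, ..., 2.5 s: 101 bins.
#'
#' @param spikeTimes list per trial of event-relative spike times covering at
#'   least `[range[1] - win/2, range[2] + win/2)` (see [spikesByTrial()]).
#' @param win window length in seconds.
#' @param step step in seconds.
#' @param range centres span `[range[1], range[2]]` inclusive.
#' @return A trials x bins integer matrix.
#' @export
slidingCounts <- function(spikeTimes, win = 0.2, step = 0.025,
                          range = c(0, 2.5)) {
  centers <- seq(range[1], range[2], by = step)
  out <- matrix(0L, length(spikeTimes), length(centers))
  for (i in seq_along(spikeTimes)) {
    st <- spikeTimes[[i]]
    if (!length(st)) next
    out[i, ] <- vapply(centers, function(cc)
      sum(st >= cc - win / 2 & st < cc + win / 2), integer(1))
  }
  colnames(out) <- sprintf("%.3f", centers)
  out
}

#' Noise correlation of a unit pair with a trial-shuffle null
#'
#' Pearson correlation of the two units' sliding-count vectors within each
#' trial, averaged over the selected trials; the null re-pairs unit A's
#' trials with a permutation of unit B's trials within each condition and
#' recomputes the average, `nShuffle` times. Zero-variance trials are skipped
#' and counted. Pairs recorded on the same channel should not be passed
#' (guarded by `sameChannel`).
#'
#' @param countsA,countsB trials x bins matrices from [slidingCounts()].
#' @param conditions factor of trial conditions the shuffle respects (e.g.
#'   category x load); default one condition.
#' @param trials logical mask of trials to use.
#' @param nShuffle shuffle repetitions for the null.
#' @param sameChannel set `TRUE` to refuse the pair.
#' @return A list with `r` (mean correlation), `null` (vector), `p`
#'   (two-sided), `band95` and `nSkipped`.
#' @export
noiseCorrelation <- function(countsA, countsB, conditions = NULL,
                             trials = NULL, nShuffle = 1000L,
                             sameChannel = FALSE) {
  if (sameChannel)
    stop("pairs recorded on the same channel are excluded")
  n <- nrow(countsA)
  if (is.null(trials)) trials <- rep(TRUE, n)
  if (is.null(conditions)) conditions <- rep(1L, n)
  conditions <- as.factor(conditions)
  idx <- which(trials)
  trialR <- function(ia, ib) {
    r <- vapply(seq_along(ia), function(k) {
      a <- countsA[ia[k], ]; b <- countsB[ib[k], ]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1))
    r
  }
  robs <- trialR(idx, idx)
  nSkipped <- sum(is.na(robs))
  rMean <- mean(robs, na.rm = TRUE)
  null <- vapply(seq_len(nShuffle), function(s) {
    ib <- idx
    for (lv in levels(conditions)) {
      j <- which(conditions[idx] == lv)
      if (length(j) > 1L) ib[j] <- ib[sample(j)]
    }
    mean(trialR(idx, ib), na.rm = TRUE)
  }, numeric(1))
  p <- (sum(abs(null - mean(null)) >= abs(rMean - mean(null))) + 1) /
    (nShuffle + 1)
  list(r = rMean, null = null, p = p,
       band95 = quantile(null, c(0.025, 0.975), names = FALSE),
       nSkipped = nSkipped)
}

#' Remove noise correlations by within-category trial shuffling
#'
#' Independently permutes each unit's trials within every category, which
#' preserves each unit's per-category count distribution exactly (same
#' multiset of rows) while destroying trial-to-trial co-fluctuations between
#' units. Labels are unchanged; categories with a single trial are left as
#' is.
#'
#' @param countsByUnit list of per-unit matrices (trials x anything) or a
#'   trials x units matrix.
#' @param labels category label per trial.
#' @return The same structure with rows permuted within category per unit.
#' @export
removeNoiseCorrelations <- function(countsByUnit, labels) {
  labels <- as.factor(labels)
  permWithin <- function() {
    p <- seq_along(labels)
    for (lv in levels(labels)) {
      j <- which(labels == lv)
      if (length(j) > 1L) p[j] <- j[sample.int(length(j))]
    }
    p
  }
  if (is.matrix(countsByUnit)) {
    out <- countsByUnit
    for (u in seq_len(ncol(out))) out[, u] <- countsByUnit[permWithin(), u]
    return(out)
  }
  lapply(countsByUnit, function(m) {
    if (is.null(dim(m))) m[permWithin()] else m[permWithin(), , drop = FALSE]
  })
}

# one multiclass accuracy evaluation: subsample to equal class counts,
# stratified 80/20 split, z-score on training stats, linear SVM (libsvm
# one-vs-one), held-out accuracy. removeCorr shuffles trials within class
# per unit before splitting.
.svmAccuracyOnce <- function(X, y, testFrac = 0.2, removeCorr = FALSE,
                             cost = 1) {
  y <- as.factor(y)
  nmin <- min(table(y))
  keep <- unlist(lapply(levels(y), function(lv)
    sample(which(y == lv), nmin)), use.names = FALSE)
  X <- X[keep, , drop = FALSE]; y <- droplevels(y[keep])
  if (removeCorr) X <- removeNoiseCorrelations(X, y)
  nTest <- max(1L, round(nmin * testFrac))
  testIdx <- unlist(lapply(levels(y), function(lv)
    sample(which(y == lv), nTest)), use.names = FALSE)
  tr <- setdiff(seq_along(y), testIdx)
  mu <- colMeans(X[tr, , drop = FALSE])
  sdv <- apply(X[tr, , drop = FALSE], 2L, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  fit <- e1071::svm(Z[tr, , drop = FALSE], y[tr], kernel = "linear",
                    cost = cost, scale = FALSE)
  mean(predict(fit, Z[testIdx, , drop = FALSE]) == y[testIdx])
}

.svmAccuracy <- function(X, y, nRep, testFrac = 0.2, removeCorr = FALSE) {
  mean(vapply(seq_len(nRep), function(r)
    .svmAccuracyOnce(X, y, testFrac, removeCorr), numeric(1)))
}

#' Greedy forward-selected ensemble decoding
#'
#' Starting from the single unit with the best held-out accuracy of a linear
#' one-versus-one SVM (cost 1, z-scored rates, trials subsampled to equal
#' class counts, stratified 80/20 splits averaged over `nRep` repetitions),
#' repeatedly adds the unit that most improves the ensemble, until all units
#' are included. Accuracy curves are reported with noise correlations intact
#' and removed (within-category trial shuffling per unit, same ensembles).
#' Ties in the greedy choice are broken by lowest unit index.
#'
#' @param rates trials x units matrix of firing rates or counts (typically
#'   maintenance-period counts of load-1 correct trials).
#' @param labels category label per trial.
#' @param nRep decoding repetitions per evaluation (default 500).
#' @param nRepSelect repetitions during greedy candidate evaluation
#'   (defaults to `nRep`).
#' @param testFrac held-out fraction.
#' @return A list with `order` (unit indices), `accIntact`, `accRemoved`
#'   (accuracy per ensemble size), `maxAcc`, `maxAccRemoved`, `bestSize`
#'   (size maximising the intact curve), `chance`.
#' @export
greedyDecoding <- function(rates, labels, nRep = 500L, nRepSelect = nRep,
                           testFrac = 0.2) {
  labels <- as.factor(labels)
  if (min(table(labels)) < 2L) stop("need at least 2 trials per category")
  nu <- ncol(rates)
  if (nu < 1L) stop("need at least one unit")
  remaining <- seq_len(nu)
  order_ <- integer(0)
  accIntact <- accRemoved <- numeric(nu)
  for (k in seq_len(nu)) {
    cand <- vapply(remaining, function(u)
      .svmAccuracy(rates[, c(order_, u), drop = FALSE], labels, nRepSelect,
                   testFrac), numeric(1))
    best <- remaining[which.max(cand)]   # which.max: first max, lowest index
    order_ <- c(order_, best)
    remaining <- setdiff(remaining, best)
    accIntact[k] <- if (nRepSelect == nRep) max(cand) else
      .svmAccuracy(rates[, order_, drop = FALSE], labels, nRep, testFrac)
    accRemoved[k] <- .svmAccuracy(rates[, order_, drop = FALSE], labels,
                                  nRep, testFrac, removeCorr = TRUE)
  }
  list(order = order_, accIntact = accIntact, accRemoved = accRemoved,
       maxAcc = max(accIntact), maxAccRemoved = max(accRemoved),
       bestSize = which.max(accIntact),
       chance = 1 / nlevels(droplevels(labels)))
}

#' Effect of removing PAC neurons on maximal decoding accuracy
#'
#' Compares the maximal greedy decoding accuracy of the full ensemble with
#' the ensemble after removing all PAC neurons, and with ensembles after
#' removing the same number of randomly chosen non-PAC neurons (averaged over
#' `nDraws` draws).
#'
#' @param rates trials x units matrix.
#' @param labels category label per trial.
#' @param pacUnits indices (or logical) of PAC neurons among the columns.
#' @param nRep decoding repetitions per greedy run.
#' @param nDraws random non-PAC removals.
#' @return A list with `maxAccFull`, `maxAccNoPac`, `maxAccRandomRemoval`
#'   (mean) and `randomDraws`.
#' @export
pacAblation <- function(rates, labels, pacUnits, nRep = 100L, nDraws = 50L) {
  nu <- ncol(rates)
  pac <- if (is.logical(pacUnits)) which(pacUnits) else pacUnits
  nonPac <- setdiff(seq_len(nu), pac)
  if (length(pac) < 1L) stop("no PAC neurons given")
  if (length(nonPac) < 2L) stop("need at least two non-PAC neurons")
  full <- greedyDecoding(rates, labels, nRep = nRep)
  noPac <- greedyDecoding(rates[, nonPac, drop = FALSE], labels, nRep = nRep)
  draws <- vapply(seq_len(nDraws), function(d) {
    drop_ <- sample(nonPac, length(pac))
    keep <- setdiff(seq_len(nu), drop_)
    greedyDecoding(rates[, keep, drop = FALSE], labels, nRep = nRep)$maxAcc
  }, numeric(1))
  list(maxAccFull = full$maxAcc, maxAccNoPac = noPac$maxAcc,
       maxAccRandomRemoval = mean(draws), randomDraws = draws)
}

# angle between two vectors folded to [0, 90] degrees
.foldedAngle <- function(a, b) {
  ca <- abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(pmin(1, ca)) * 180 / pi
}

#' Signal/noise-axis geometry of a population response
#'
#' For each repetition and each binary (one-versus-one) class pair: trains a
#' linear SVM on z-scored rates of 80% of the equal-count trials; takes the
#' signal axis as the unit normal of the decision boundary; takes the noise
#' axis as the first principal component of the class-mean-centred responses;
#' and records the angle between them, folded to [0, 90] degrees. Projection
#' variability is the s.d. of the responses projected on the signal axis,
#' averaged across classes. Everything is averaged across binary learners and
#' repetitions, separately with noise correlations intact and removed.
#'
#' @param rates trials x units matrix.
#' @param labels category label per trial.
#' @param ensemble column indices of the ensemble to analyse (e.g. the greedy
#'   ensemble at which the intact-removed decoding difference peaks).
#' @param nRep repetitions (default 500).
#' @param testFrac held-out fraction (the axes use the training portion).
#' @param center centre by class means before the noise PCA (default TRUE;
#'   FALSE reproduces the uncentred variant).
#' @param zscore z-score rates on training statistics before fitting
#'   (default FALSE: the axes live in raw firing-rate space, where the
#'   variance structure that defines the noise axis is preserved; per-unit
#'   z-scoring absorbs each unit's signal variance into its normalisation
#'   and distorts the noise principal component).
#' @return A list with `angleIntact`, `angleRemoved`, `projSdIntact`,
#'   `projSdRemoved`.
#' @export
signalNoiseGeometry <- function(rates, labels, ensemble = seq_len(ncol(rates)),
                                nRep = 500L, testFrac = 0.2, center = TRUE,
                                zscore = FALSE) {
  labels <- as.factor(labels)
  X0 <- rates[, ensemble, drop = FALSE]
  if (ncol(X0) < 2L) stop("geometry needs at least 2 units in the ensemble")
  pairsMat <- utils::combn(levels(labels), 2L)
  run <- function(removeCorr) {
    ang <- sdv <- numeric(0)
    for (r in seq_len(nRep)) {
      y <- labels
      nmin <- min(table(y))
      keep <- unlist(lapply(levels(y), function(lv)
        sample(which(y == lv), nmin)), use.names = FALSE)
      X <- X0[keep, , drop = FALSE]; yk <- droplevels(y[keep])
      if (removeCorr) X <- removeNoiseCorrelations(X, yk)
      nTest <- max(1L, round(nmin * testFrac))
      testIdx <- unlist(lapply(levels(yk), function(lv)
        sample(which(yk == lv), nTest)), use.names = FALSE)
      tr <- setdiff(seq_along(yk), testIdx)
      mu <- colMeans(X[tr, , drop = FALSE])
      s <- if (zscore) apply(X[tr, , drop = FALSE], 2L, sd) else
        rep(1, ncol(X))
      s[s == 0] <- 1
      Z <- sweep(sweep(X, 2L, mu), 2L, s, "/")
      for (pp in seq_len(ncol(pairsMat))) {
        sel <- tr[yk[tr] %in% pairsMat[, pp]]
        if (length(unique(yk[sel])) < 2L) next
        Ztr <- Z[sel, , drop = FALSE]
        ytr <- droplevels(yk[sel])
        fit <- tryCatch(
          e1071::svm(Ztr, ytr, kernel = "linear", cost = 1, scale = FALSE),
          error = function(e) NULL)
        if (is.null(fit)) next
        w <- as.vector(t(fit$coefs) %*% fit$SV)
        if (all(w == 0)) next
        w <- w / sqrt(sum(w^2))
        Zc <- Ztr
        if (center)
          for (lv in levels(ytr))
            Zc[ytr == lv, ] <- sweep(Ztr[ytr == lv, , drop = FALSE], 2L,
                                     colMeans(Ztr[ytr == lv, , drop = FALSE]))
        pc <- tryCatch(prcomp(Zc, center = !center, scale. = FALSE),
                       error = function(e) NULL)
        if (is.null(pc)) next
        ang <- c(ang, .foldedAngle(w, pc$rotation[, 1]))
        proj <- Ztr %*% w
        sdv <- c(sdv, mean(vapply(levels(ytr), function(lv)
          sd(proj[ytr == lv]), numeric(1))))
      }
    }
    if (!length(ang)) stop("rank-deficient data for ensemble (",
                           paste(ensemble, collapse = ","), ")")
    c(angle = mean(ang), projSd = mean(sdv, na.rm = TRUE))
  }
  ri <- run(FALSE); rr <- run(TRUE)
  list(angleIntact = ri[["angle"]], angleRemoved = rr[["angle"]],
       projSdIntact = ri[["projSd"]], projSdRemoved = rr[["projSd"]])
}

#' Noise-correlation contrast between fast and slow RT trials
#'
#' For each unit pair, splits the selected trials into fast and slow by the
#' median reaction time computed separately within each load (ties to fast),
#' averages the per-trial count correlation within each split and load, then
#' averages across loads; reports the paired fast-minus-slow contrast across
#' pairs. A control set of random pairings of the same size can be passed
#' through `controlPairs`.
#'
#' @param pairList list of pairs, each `list(a = countsA, b = countsB)`
#'   (trials x bins matrices aligned with `rt`/`load`).
#' @param rt reaction times per trial (seconds).
#' @param load load per trial (1 or 3).
#' @param trials logical mask (e.g. correct trials of the preferred
#'   category).
#' @param minTrials minimum trials per split; pairs under it are excluded.
#' @param nPerm permutations for the paired test.
#' @return A list with `perPair` (fast, slow, diff per pair), `t`, `p`,
#'   `nExcluded`.
#' @export
rtSplitCorrelations <- function(pairList, rt, load, trials = NULL,
                                minTrials = 5L, nPerm = 10000L) {
  n <- length(rt)
  if (is.null(trials)) trials <- rep(TRUE, n)
  fast <- rep(NA, n)
  for (ld in unique(load)) {
    j <- which(trials & load == ld)
    if (!length(j)) next
    fast[j] <- rt[j] <= median(rt[j])
  }
  rows <- list(); nExcluded <- 0L
  for (pp in pairList) {
    meanR <- function(sel) {
      r <- vapply(which(sel), function(i) {
        a <- pp$a[i, ]; b <- pp$b[i, ]
        if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
        cor(a, b)
      }, numeric(1))
      mean(r, na.rm = TRUE)
    }
    byLoad <- function(isFast) {
      v <- vapply(unique(load), function(ld) {
        sel <- trials & load == ld & (fast %in% isFast)
        if (sum(sel) < minTrials) return(NA_real_)
        meanR(sel)
      }, numeric(1))
      mean(v, na.rm = FALSE)
    }
    fa <- byLoad(TRUE); sl <- byLoad(FALSE)
    if (is.na(fa) || is.na(sl)) { nExcluded <- nExcluded + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(fast = fa, slow = sl,
                                            diff = fa - sl)
  }
  perPair <- do.call(rbind, rows)
  if (is.null(perPair) || nrow(perPair) < 2L)
    return(list(perPair = perPair, t = NA_real_, p = NA_real_,
                nExcluded = nExcluded))
  tt <- permTTest(perPair$fast, perPair$slow, paired = TRUE, nPerm = nPerm)
  list(perPair = perPair, t = tt$t, p = tt$p, nExcluded = nExcluded)
}
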