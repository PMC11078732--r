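# Category-cell and PAC-neuron identification.

# picture presentations (encoding + probe) with category labels and onsets
.presentations <- function(trials) {
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    for (k in seq_len(tr$load)) {
      on <- tr[[paste0("picture_onset", k)]]
      cat <- tr[[paste0("cat", k)]]
      if (!is.na(on) && !is.na(cat))
        rows[[length(rows) + 1L]] <- data.frame(trial = i, onset = on,
                                                category = cat)
    }
    if (!is.null(tr$probe_category) && !is.na(tr$probe_category))
      rows[[length(rows) + 1L]] <- data.frame(trial = i, onset = tr$probe_onset,
                                              category = tr$probe_category)
  }
  do.call(rbind, rows)
}

.presentationCounts <- function(timestamps, presentations,
                                window = c(0.2, 1.0)) {
  vapply(presentations$onset, function(on)
    sum(timestamps >= on + window[1] & timestamps < on + window[2]),
    integer(1))
}

#' Select category-tuned neurons
#'
#' Counts each unit's spikes 200-1000 ms after every picture onset (all
#' encoding presentations and the probe), runs a 1 x 5 permutation ANOVA over
#' the five categories, and a post-hoc one-sided permutation t-test of the
#' maximum-count category against each other category; a unit is a category
#' neuron if the ANOVA and all post-hoc tests are significant at `alpha`. An
#' area-level null repeats the whole selection `nNull` times with category
#' labels shuffled across presentations and compares the observed count to
#' the null's 99th percentile.
#'
#' @param session a [Session-class].
#' @param nPerm permutations for the ANOVA and post-hoc tests (default 2000).
#' @param nNull label-shuffle repetitions for the population null (default
#'   500; 0 skips it).
#' @param alpha per-test significance level.
#' @param window count window after stimulus onset, seconds.
#' @param minPresentations units with fewer presentations are excluded.
#' @return A list with `tuning` (data frame per unit: `anova_p`,
#'   `posthoc_p` (max over comparisons), `preferred_category`, `selected`)
#'   and, if `nNull > 0`, `areaNull` (per area: observed, critical, p,
#'   significant).
#' @export
selectCategoryNeurons <- function(session, nPerm = 2000L, nNull = 500L,
                                  alpha = 0.05, window = c(0.2, 1.0),
                                  minPresentations = 10L) {
  pres <- .presentations(session@trials)
  counts <- lapply(session@units, function(u)
    .presentationCounts(u@timestamps, pres, window))
  selectOne <- function(cnt, labels) {
    if (length(cnt) < minPresentations || all(cnt == cnt[1]))
      return(list(anova_p = NA_real_, posthoc_p = NA_real_,
                  preferred = NA_integer_, selected = FALSE))
    av <- permAnova(cnt, labels, nPerm)
    mu <- tapply(cnt, labels, mean)
    pref <- as.integer(names(mu)[which.max(mu)])
    others <- setdiff(unique(labels), pref)
    pp <- vapply(others, function(o)
      permTTest(cnt[labels == pref], cnt[labels == o], nPerm = nPerm,
                sided = "greater")$p, numeric(1))
    list(anova_p = av$p, posthoc_p = max(pp), preferred = pref,
         selected = av$p < alpha && all(pp < alpha))
  }
  res <- lapply(counts, selectOne, labels = pres$category)
  tuning <- data.frame(
    unit_id = names(session@units),
    region = vapply(session@units, function(u) u@region, character(1)),
    anova_p = vapply(res, `[[`, numeric(1), "anova_p"),
    posthoc_p = vapply(res, `[[`, numeric(1), "posthoc_p"),
    preferred_category = vapply(res, `[[`, integer(1), "preferred"),
    selected = vapply(res, `[[`, logical(1), "selected"),
    row.names = NULL)
  out <- list(tuning = tuning)
  if (nNull > 0L) {
    areas <- unique(tuning$region)
    nullCounts <- matrix(0L, nNull, length(areas),
                         dimnames = list(NULL, areas))
    for (r in seq_len(nNull)) {
      lab <- sample(pres$category)
      sel <- vapply(counts, function(cnt)
        selectOne(cnt, lab)$selected, logical(1))
      for (a in areas)
        nullCounts[r, a] <- sum(sel & tuning$region == a)
    }
    out$areaNull <- do.call(rbind, lapply(areas, function(a) {
      obs <- sum(tuning$selected & tuning$region == a)
      pr <- proportionAboveNull(obs, nullCounts[, a])
      data.frame(area = a, observed = obs, critical = pr$critical,
                 p = pr$p, significant = pr$significant)
    }))
  }
  out
}

#' Average z-scored gamma amplitude from a fixed-cycle wavelet bank
#'
#' Gamma amplitude for the PAC-neuron design: Morlet wavelets at 70-140 Hz in
#' 5 Hz steps, 7 cycles each; each frequency's amplitude is z-scored across
#' all trials and time points (avoiding the 1/f bias toward low frequencies)
#' and then averaged across frequencies.
#'
#' @param epochs an [LFPEpochs-class].
#' @param freqs gamma frequencies in Hz.
#' @param cycles wavelet cycles (fixed).
#' @param trim analysis window.
#' @return A trials x time matrix of average z-scored gamma amplitude.
#' @export
gammaAmplitudeAverage <- function(epochs, freqs = seq(70, 140, 5),
                                  cycles = 7, trim = c(0, 2.5)) {
  kernels <- lapply(freqs, function(f) {
    sdt <- cycles / (2 * pi * f)
    half <- ceiling(4 * sdt * epochs@fs)
    t <- seq(-half, half) / epochs@fs
    k <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sdt^2))
    k / sqrt(sum(Mod(k)^2))
  })
  bank <- new("MorletBank", freqs = freqs,
              cycles = rep(cycles, length(freqs)), fs = epochs@fs,
              kernels = kernels)
  wt <- waveletTransform(epochs, bank, trim = trim)
  ntr <- dim(wt$coef)[1]; nt <- dim(wt$coef)[3]
  acc <- matrix(0, ntr, nt)
  for (f in seq_along(freqs)) {
    am <- Mod(wt$coef[, f, ])
    mu <- mean(am, na.rm = TRUE); sdv <- sd(as.vector(am), na.rm = TRUE)
    acc <- acc + (am - mu) / sdv
  }
  acc / length(freqs)
}

#' Build the 20-bin theta-phase by gamma-amplitude spike-count design
#'
#' Concatenates theta phase (3-7 Hz Hilbert) and average z-scored gamma
#' amplitude across the selected trials, median-splits the gamma amplitude
#' into low/high, bins theta phase into `nPhaseBins` 36-degree bins within
#' each gamma half, and counts the unit's spikes per bin. Occupancy (time
#' spent per bin) is recorded for use as a GLM exposure offset.
#'
#' @param spikeTimes list per trial of event-relative spike times.
#' @param thetaPhase trials x time matrix of theta phase over `trim`.
#' @param gammaAmp trials x time matrix of average z-scored gamma amplitude.
#' @param trials logical mask of trials to use (correct trials of one load).
#' @param fs sampling rate.
#' @param nPhaseBins theta-phase bins (default 10).
#' @param trim analysis window.
#' @return A data frame with 2 x `nPhaseBins` rows: `phaseBin`,
#'   `phaseCenter` (radians), `gamma` (0 low / 1 high), `count`, `exposure`
#'   (seconds), `occupancy` (samples).
#' @export
buildPhaseGammaDesign <- function(spikeTimes, thetaPhase, gammaAmp, trials,
                                  fs, nPhaseBins = 10L, trim = c(0, 2.5)) {
  use <- which(trials & !apply(thetaPhase, 1L, anyNA))
  ph <- as.vector(t(thetaPhase[use, , drop = FALSE]))
  ga <- as.vector(t(gammaAmp[use, , drop = FALSE]))
  gHigh <- ga > median(ga)
  pbin <- .phaseBin(ph, nPhaseBins)
  nt <- ncol(thetaPhase)
  # spike sample indices into the concatenated stream
  sidx <- integer(0)
  for (j in seq_along(use)) {
    st <- spikeTimes[[use[j]]]
    if (!length(st)) next
    k <- round((st - trim[1]) * fs) + 1L
    k <- k[k >= 1L & k <= nt]
    sidx <- c(sidx, (j - 1L) * nt + k)
  }
  cell <- (as.integer(gHigh)) * nPhaseBins + pbin   # 1..2*nPhaseBins
  occ <- tabulate(cell, 2L * nPhaseBins)
  cnt <- tabulate(cell[sidx], 2L * nPhaseBins)
  centers <- -pi + (seq_len(nPhaseBins) - 0.5) * 2 * pi / nPhaseBins
  data.frame(phaseBin = rep(seq_len(nPhaseBins), 2L),
             phaseCenter = rep(centers, 2L),
             gamma = rep(c(0L, 1L), each = nPhaseBins),
             count = cnt, occupancy = occ, exposure = occ / fs)
}

#' Fit the three nested Poisson spike-count models
#'
#' Model 1 regresses the per-bin spike count on cos/sin of the theta-phase
#' bin centre, the gamma half (low/high), and the phase x gamma interaction;
#' model 2 drops the interaction; model 3 drops the gamma main effect.
#' Likelihood-ratio tests of model 1 against models 2 (2 df) and 3 (1 df)
#' isolate units whose firing follows the theta-phase x gamma-amplitude
#' interaction beyond either main effect (the model-3 comparison guards
#' against spurious interactions created by strong field-level PAC in the
#' absence of any spike coupling). By default counts are modelled with a
#' log-occupancy exposure offset so unequal bin occupancy cannot masquerade
#' as a phase effect; `offset = FALSE` reproduces the raw-count variant.
#'
#' @param design a data frame from [buildPhaseGammaDesign()].
#' @param offset use log-exposure offset (default TRUE).
#' @return A list with `deviance` (m1, m2, m3), `lr` (statistics), `p`
#'   (`p12`, `p13`), `r2` (squared correlation of observed and model-1
#'   fitted counts), `r2Deviance` (pseudo R-squared alternative), `fits`.
#' @export
fitPacModels <- function(design, offset = TRUE) {
  d <- design[design$occupancy > 0L, , drop = FALSE]
  if (sum(d$count) < 1L) stop("design contains no spikes")
  d$tc <- cos(d$phaseCenter); d$ts <- sin(d$phaseCenter)
  off <- if (offset) log(d$exposure) else rep(0, nrow(d))
  f1 <- glm(count ~ tc + ts + gamma + tc:gamma + ts:gamma,
            family = poisson(), data = d, offset = off)
  f2 <- glm(count ~ tc + ts + gamma, family = poisson(), data = d,
            offset = off)
  f3 <- glm(count ~ tc + ts + tc:gamma + ts:gamma, family = poisson(),
            data = d, offset = off)
  lr12 <- max(0, f2$deviance - f1$deviance)
  lr13 <- max(0, f3$deviance - f1$deviance)
  null <- glm(count ~ 1, family = poisson(), data = d, offset = off)
  list(deviance = c(m1 = f1$deviance, m2 = f2$deviance, m3 = f3$deviance),
       lr = c(lr12 = lr12, lr13 = lr13),
       p = c(p12 = pchisq(lr12, 2, lower.tail = FALSE),
             p13 = pchisq(lr13, 1, lower.tail = FALSE)),
       r2 = cor(d$count, fitted(f1))^2,
       r2Deviance = 1 - f1$deviance / null$deviance,
       fits = list(m1 = f1, m2 = f2, m3 = f3))
}

# internal: per-unit PAC-neuron decision across channels and loads.
# phaseAmpByChannel: named list per channel of list(theta=, gamma=) matrices.
.pacNeuronOne <- function(spikeTimes, phaseAmpByChannel, loadMasks, fs,
                          alpha = 0.01, offset = TRUE,
                          trialPermutation = NULL, trim = c(0, 2.5)) {
  combos <- expand.grid(channel = names(phaseAmpByChannel),
                        load = names(loadMasks), stringsAsFactors = FALSE)
  p12 <- p13 <- r2 <- rep(NA_real_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pa <- phaseAmpByChannel[[combos$channel[i]]]
    mask <- loadMasks[[combos$load[i]]]
    st <- spikeTimes
    if (!is.null(trialPermutation)) st <- spikeTimes[trialPermutation]
    des <- buildPhaseGammaDesign(st, pa$theta, pa$gamma, mask, fs,
                                 trim = trim)
    if (sum(des$count) < 1L) next
    fit <- tryCatch(fitPacModels(des, offset = offset),
                    error = function(e) NULL)
    if (is.null(fit)) next
    p12[i] <- fit$p["p12"]; p13[i] <- fit$p["p13"]; r2[i] <- fit$r2
  }
  # FDR across channel combinations, within each load and test family
  sel <- rep(FALSE, nrow(combos))
  for (ld in names(loadMasks)) {
    j <- combos$load == ld & is.finite(p12)
    if (!any(j)) next
    m12 <- fdrMask(p12[j], alpha)$mask
    m13 <- fdrMask(p13[j], alpha)$mask
    sel[which(j)[m12 & m13]] <- TRUE
  }
  chosen <- NA_character_
  if (any(sel)) {
    qual <- which(sel)
    chosen <- combos$channel[qual[which.max(r2[qual])]]
  }
  list(selected = any(sel), chosenChannel = chosen, combos = combos,
       p12 = p12, p13 = p13, r2 = r2)
}

#' Select PAC neurons from a session
#'
#' For every unit and every same-region channel, builds the 20-bin design
#' separately per load on correct trials, fits the three Poisson models, and
#' flags the unit as a PAC neuron if both likelihood-ratio tests survive
#' Benjamini-Hochberg correction across the unit's channel combinations at
#' `alpha` in either load for at least one combination. Among qualifying
#' combinations the channel with the highest model-1 R-squared is retained.
#'
#' @param session a [Session-class].
#' @param alpha FDR-adjusted significance level (default 0.01).
#' @param offset use the log-occupancy exposure offset.
#' @param trim analysis window.
#' @param channels optional character vector restricting the LFP channels.
#' @return A list with `selection` (data frame per unit: selected,
#'   chosen_channel), `details` (per-unit combo tables), and the
#'   phase/amplitude matrices in `fields` (reused by [pacSelectionNull()]).
#' @export
selectPacNeurons <- function(session, alpha = 0.01, offset = TRUE,
                             trim = c(0, 2.5), channels = NULL) {
  tr <- session@trials
  loadMasks <- list(load1 = tr$correct & tr$load == 1L,
                    load3 = tr$correct & tr$load == 3L)
  chs <- if (is.null(channels)) names(session@lfp) else channels
  fields <- lapply(session@lfp[chs], function(ep)
    list(theta = hilbertPhaseAmp(ep, c(3, 7), trim)$phase,
         gamma = gammaAmplitudeAverage(ep, trim = trim),
         region = ep@region, valid = ep@validTrials))
  fs <- session@lfp[[chs[1]]]@fs
  rows <- list(); details <- list()
  for (uid in names(session@units)) {
    u <- session@units[[uid]]
    reg <- vapply(fields, `[[`, character(1), "region")
    mine <- fields[reg == u@region]
    if (!length(mine)) next
    st <- spikesByTrial(u@timestamps, tr$maintenance_onset, trim)$times
    masks <- lapply(loadMasks, function(m)
      m & Reduce(`&`, lapply(mine, `[[`, "valid")))
    res <- .pacNeuronOne(st, mine, masks, fs, alpha, offset)
    rows[[uid]] <- data.frame(unit_id = uid, region = u@region,
                              selected = res$selected,
                              chosen_channel = res$chosenChannel)
    details[[uid]] <- res
  }
  list(selection = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       details = details, fields = fields, loadMasks = loadMasks, fs = fs,
       alpha = alpha, offset = offset, trim = trim)
}

#' Population null for the PAC-neuron selection
#'
#' Repeats the entire PAC-neuron selection after re-pairing each unit's
#' per-trial spike trains with the LFP of a different, randomly chosen trial
#' (destroying the spike-field relationship while preserving per-trial spike
#' counts), and reports, per area, the fraction of repetitions with at least
#' as many selected neurons as observed ((b+1)/(m+1) corrected).
#'
#' @param session a [Session-class].
#' @param observed result of [selectPacNeurons()] on the same session.
#' @param nRep shuffle repetitions (default 200).
#' @return Data frame per area: observed count, `p`.
#' @export
pacSelectionNull <- function(session, observed, nRep = 200L) {
  tr <- session@trials
  fields <- observed$fields
  fs <- observed$fs
  areas <- unique(observed$selection$region)
  obsCount <- vapply(areas, function(a)
    sum(observed$selection$selected & observed$selection$region == a),
    integer(1))
  nullCounts <- matrix(0L, nRep, length(areas),
                       dimnames = list(NULL, areas))
  ntr <- nrow(tr)
  for (r in seq_len(nRep)) {
    perm <- sample.int(ntr)
    for (uid in names(session@units)) {
      u <- session@units[[uid]]
      reg <- vapply(fields, `[[`, character(1), "region")
      mine <- fields[reg == u@region]
      if (!length(mine)) next
      st <- spikesByTrial(u@timestamps, tr$maintenance_onset,
                          observed$trim)$times
      masks <- lapply(observed$loadMasks, function(m)
        m & Reduce(`&`, lapply(mine, `[[`, "valid")))
      res <- .pacNeuronOne(st, mine, masks, fs, observed$alpha,
                           observed$offset, trialPermutation = perm)
      if (res$selected)
        nullCounts[r, u@region] <- nullCounts[r, u@region] + 1L
    }
  }
  do.call(rbind, lapply(seq_along(areas), function(i)
    data.frame(area = areas[i], observed = obsCount[i],
               p = (sum(nullCounts[, i] >= obsCount[i]) + 1) / (nRep + 1))))
}

#' Overlap test between PAC-neuron and category-neuron selections
#'
#' Hypergeometric (right-tail) probability of observing at least the given
#' overlap if the two selections were independent draws from the same unit
#' universe.
#'
#' @param selectedPac,selectedCat character vectors of selected unit ids.
#' @param nTotal size of the unit universe.
#' @return A list with `overlap`, `expected` and `p`.
#' @export
overlapIndependenceTest <- function(selectedPac, selectedCat, nTotal) {
  k <- length(intersect(selectedPac, selectedCat))
  K <- length(unique(selectedPac)); n <- length(unique(selectedCat))
  if (K == 0L || n == 0L) return(list(overlap = k, expected = 0, p = 1))
  list(overlap = k, expected = K * n / nTotal,
       p = phyper(k - 1, K, nTotal - K, n, lower.tail = FALSE))
}
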