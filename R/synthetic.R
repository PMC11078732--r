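# Synthetic sessions with known ground truth.
#
# The generator emulates the study conditions: 140 trials split 70/70 across
# loads 1 and 3, five stimulus categories, a 2.5-s maintenance window
# analysed within a [-0.5, 3.0) s epoch, LFP = pink (1/f^1.75) background +
# theta sinusoid + broadband gamma bursts whose instantaneous amplitude is a
# cosine function of theta phase, and spike trains with category gains,
# von-Mises theta locking, theta-phase x gamma-amplitude interaction firing,
# and shared-gain trial-to-trial noise correlations.

#' Default per-unit specifications for the synthetic session
#'
#' A mixed population: category-tuned units (gain on one preferred category),
#' PAC-interacting units (`betaInt > 0`, mild locking), theta-locked-only
#' units, and null units. All units share gain group 1 so shared-gain noise
#' correlations exist by default.
#'
#' @param nTuned,nPac,nLocked,nNull counts per ground-truth class.
#' @param region,channelId labels applied to every unit.
#' @return A data frame, one row per unit: `unit_id`, `region`,
#'   `channel_id`, `baseRate` (Hz), `gain1..gain5`, `kappaVm`, `phasePref`,
#'   `betaInt` (theta-phase by gamma-amplitude interaction gain),
#'   `betaGamma` (gamma main-effect log-gain), `sharedGroup`.
#' @export
defaultUnitSpecs <- function(nTuned = 4L, nPac = 4L, nLocked = 2L,
                             nNull = 2L, region = "hippocampus",
                             channelId = "chS") {
  n <- nTuned + nPac + nLocked + nNull
  gains <- matrix(1, n, 5L)
  kappa <- beta <- betaG <- numeric(n)
  for (i in seq_len(nTuned)) gains[i, (i - 1L) %% 5L + 1L] <- 3
  if (nPac > 0L) {
    j <- nTuned + seq_len(nPac)
    beta[j] <- 1.5
    betaG[j] <- 0.8   # PAC neurons also fire more during gamma bursts
    kappa[j] <- 0.5
  }
  if (nLocked > 0L) kappa[nTuned + nPac + seq_len(nLocked)] <- 1
  out <- data.frame(unit_id = sprintf("u%02d", seq_len(n)), region = region,
                    channel_id = channelId, baseRate = 5,
                    kappaVm = kappa, phasePref = 0, betaInt = beta,
                    betaGamma = betaG, sharedGroup = 1L)
  for (k in 1:5) out[[paste0("gain", k)]] <- gains[, k]
  out
}

#' Configuration of the synthetic-session generator
#'
#' Defaults are the study conditions; every parameter can be overridden.
#' Amplitudes are in microvolts; rates in Hz; `pacDepth` is the fraction of
#' the gamma amplitude modulated by theta phase per load (load 1 stronger
#' than load 3, the direction of the load effect to be recovered).
#'
#' @param ... overrides of the default fields.
#' @return A list of class `pacwmConfig`.
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    nTrials = 140L, loadSplit = c(70L, 70L), nCategories = 5L,
    fs = 400, epochWindow = c(-0.5, 3.0),
    thetaFreq = 5, thetaAmp = 15,
    pacDepth = c(load1 = 0.8, load3 = 0.4), pacPhasePref = 0,
    pacTrialSd = 0.3,
    gammaBand = c(70, 140), gammaAmp = 5, gammaBurstSd = 0.5,
    oneOverFExponent = 1.75, noiseAmp = 10,
    nChannels = 1L, region = "hippocampus",
    unitSpecs = defaultUnitSpecs(),
    sharedGainSd = 0.2, maxRate = 200,
    rtModel = list(intercept = 1.2, loadEffect = 0.3, pacSlope = 0,
                   sd = 0.25, minRt = 0.25),
    accuracy = 0.92,
    seed = 1L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  if (any(cfg$pacDepth < 0) || any(cfg$pacDepth > 1))
    stop("pacDepth must lie in [0, 1]")
  if (cfg$sharedGainSd < 0) stop("sharedGainSd must be non-negative")
  if (cfg$fs <= 2 * max(cfg$gammaBand))
    stop("fs must exceed twice the top gamma frequency")
  class(cfg) <- "pacwmConfig"
  cfg
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file of overrides for [syntheticConfig()].
#' @return A `pacwmConfig` list.
#' @export
readSyntheticConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(syntheticConfig, yaml::read_yaml(path))
}

# 1/f^a noise via spectral shaping, unit RMS
.pinkNoise <- function(n, exponent, fs) {
  nf <- n %/% 2L
  f <- seq_len(nf) * fs / n
  amp <- f^(-exponent / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, if (n %% 2L == 0L) Conj(rev(spec[-nf])) else
    Conj(rev(spec)))
  x <- Re(fft(full, inverse = TRUE))
  x <- x[seq_len(n)]
  x / sd(x)
}

#' Build a synthetic trial table
#'
#' 140 trials (70 per load by default) with five categories; load-3 trials
#' carry three distinct categories; probes are match/non-match with recorded
#' `probe_category`; reaction times follow the configured RT model
#' (optionally decreasing in trial-wise PAC strength) and accuracy is
#' Bernoulli.
#'
#' @param config a `pacwmConfig`.
#' @param kappaTrial optional per-trial PAC depth (for the RT coupling);
#'   computed internally by [simulateSession()].
#' @return A trial table data frame (see [Session-class]).
#' @export
simulateTrialTable <- function(config, kappaTrial = NULL) {
  n <- config$nTrials
  loads <- sample(rep(c(1L, 3L), config$loadSplit))
  tTrial <- 14
  rows <- lapply(seq_len(n), function(i) {
    start <- (i - 1) * tTrial
    ld <- loads[i]
    cats <- sample.int(config$nCategories, ld)
    pons <- start + 1 + (seq_len(ld) - 1) * 2.1
    maint <- pons[ld] + 2 + 0.1
    probe <- maint + 2.6
    match <- runif(1) < 0.5
    probeCat <- if (match) cats[sample.int(ld, 1L)] else
      sample(setdiff(seq_len(config$nCategories), cats), 1L)
    data.frame(trial_id = i, load = ld,
               cat1 = cats[1], cat2 = if (ld >= 2L) cats[2] else NA_integer_,
               cat3 = if (ld >= 3L) cats[3] else NA_integer_,
               probe_category = probeCat, correct = TRUE, rt = 1,
               trial_start = start,
               picture_onset1 = pons[1],
               picture_onset2 = if (ld >= 2L) pons[2] else NA_real_,
               picture_onset3 = if (ld >= 3L) pons[3] else NA_real_,
               maintenance_onset = maint, probe_onset = probe)
  })
  tr <- do.call(rbind, rows)
  rtm <- config$rtModel
  pacZ <- if (is.null(kappaTrial)) rep(0, n) else
    as.vector(scale(kappaTrial))
  rt <- rtm$intercept + rtm$loadEffect * (tr$load == 3L) +
    rtm$pacSlope * pacZ + rnorm(n, 0, rtm$sd)
  tr$rt <- pmax(rtm$minRt, rt)
  tr$correct <- runif(n) < config$accuracy
  tr
}

#' Simulate phase-amplitude-coupled LFP epochs
#'
#' Per trial: pink (1/f) background + theta sinusoid with random starting
#' phase + a band-limited gamma noise carrier whose instantaneous amplitude
#' is `gammaAmp * (1 + kappa * cos(theta_phase - pacPhasePref))`, with
#' `kappa` the trial's PAC depth (per-load value times log-normal-free
#' trial jitter, clipped to [0, 1]).
#'
#' @param config a `pacwmConfig`.
#' @param trials a trial table from [simulateTrialTable()].
#' @param channelId channel label.
#' @return A list with `epochs` ([LFPEpochs-class] over
#'   `config$epochWindow`) and `truth` (theta phase and gamma envelope
#'   matrices over the epoch window, `kappaTrial`, `phiPref`).
#' @export
simulateLfp <- function(config, trials, channelId = "ch1") {
  fs <- config$fs
  w <- config$epochWindow
  nt <- round(diff(w) * fs)
  n <- nrow(trials)
  tgrid <- w[1] + (seq_len(nt) - 1) / fs
  kapLoad <- ifelse(trials$load == 1L, config$pacDepth[["load1"]],
                    config$pacDepth[["load3"]])
  kapTrial <- pmin(1, pmax(0, kapLoad *
    (1 + config$pacTrialSd * rnorm(n))))
  samples <- thetaPhase <- gammaEnv <- matrix(NA_real_, n, nt)
  carrierKernel <- firKernel("pass", config$gammaBand, fs,
                             maxLength = 2L * (nt %/% 2L) - 1L)
  for (i in seq_len(n)) {
    phi0 <- runif(1, -pi, pi)
    th <- 2 * pi * config$thetaFreq * tgrid + phi0
    theta <- config$thetaAmp * cos(th)
    carrier <- convSame(rnorm(nt), carrierKernel)
    carrier <- carrier / sd(carrier)
    # stochastic burst modulation: slow log-normal envelope fluctuation, so
    # gamma amplitude varies beyond its theta-phase dependence
    burst <- zeroPhaseFilter(rnorm(nt), fs, "low", 10)
    burst <- exp(config$gammaBurstSd * burst / sd(burst) -
                 config$gammaBurstSd^2 / 2)
    env <- config$gammaAmp * burst *
      (1 + kapTrial[i] * cos(th - config$pacPhasePref))
    pink <- config$noiseAmp * .pinkNoise(nt, config$oneOverFExponent, fs)
    samples[i, ] <- pink + theta + env * carrier
    thetaPhase[i, ] <- ((th + pi) %% (2 * pi)) - pi
    gammaEnv[i, ] <- env
  }
  list(epochs = LFPEpochs(channelId, config$region, fs, samples, w),
       truth = list(thetaPhase = thetaPhase, gammaEnv = gammaEnv,
                    kappaTrial = kapTrial, phiPref = config$pacPhasePref))
}

# geometric-mean category gain of the maintained items
.maintGain <- function(spec, trials, i) {
  cats <- stats::na.omit(unlist(trials[i, c("cat1", "cat2", "cat3")]))
  exp(mean(log(vapply(cats, function(k)
    spec[[paste0("gain", k)]], numeric(1)))))
}

#' Simulate spike trains coupled to the synthetic LFP
#'
#' During maintenance the rate on the LFP time grid is
#' `base * g_cat * exp(kappaVm * cos(theta - phasePref) +
#' (betaInt * cos(theta) + betaGamma) * 1[gamma envelope above its trial
#' median]) * G` (a PAC neuron both fires more during gamma bursts and
#' shifts its theta phase preference with them). The shared gain `G` has a
#' trial-constant log-normal component (driving across-trial count
#' correlations) and a slow (below 1 Hz) within-trial log-normal component
#' shared by all units of the group (driving within-trial bin-to-bin noise
#' correlations), both with log-s.d. `sharedGainSd`. Spikes
#' with `G = exp(sharedGainSd * eta - sharedGainSd^2 / 2)` a trial-wise gain
#' shared by all units of the same group (the source of noise correlations);
#' spikes are drawn by Bernoulli thinning at the LFP resolution. Rates are
#' capped at `maxRate` (cap occurrences counted). Outside maintenance the
#' rate is piecewise homogeneous: `base * gain(category)` during each picture
#' presentation and the probe, `base` elsewhere; the shared gain applies
#' throughout.
#'
#' @param config a `pacwmConfig`.
#' @param trials trial table.
#' @param lfpTruth the `truth` element of [simulateLfp()] for the coupled
#'   channel.
#' @return A list with `units` (named list of [SpikeTrain-class]),
#'   `groundTruth` (data frame of per-unit labels), `sharedGain` (trial x
#'   group matrix) and `nCapped`.
#' @export
simulateSpikes <- function(config, trials, lfpTruth) {
  fs <- config$fs
  w <- config$epochWindow
  specs <- config$unitSpecs
  n <- nrow(trials)
  groups <- sort(unique(specs$sharedGroup[specs$sharedGroup > 0L]))
  ng <- max(1L, length(groups))
  sg <- config$sharedGainSd
  eta <- matrix(rnorm(n * ng), n)
  G <- exp(sg * eta - sg^2 / 2)
  colnames(G) <- if (length(groups)) as.character(groups) else "1"
  nt <- ncol(lfpTruth$thetaPhase)
  tgrid <- w[1] + (seq_len(nt) - 1) / fs
  maintIdx <- tgrid < 2.5   # thinning covers [-0.5, 2.5) of the epoch grid
  # slow (<= 1 Hz) shared log-normal gain fluctuation within each trial: the
  # source of within-trial count co-fluctuations between group members
  Gslow <- array(1, c(n, ng, nt))
  if (sg > 0) {
    for (gi in seq_len(ng)) for (i in seq_len(n)) {
      b <- zeroPhaseFilter(rnorm(nt), fs, "low", 1)
      Gslow[i, gi, ] <- exp(sg * b / sd(b) - sg^2 / 2)
    }
  }
  nCapped <- 0L
  units <- list()
  for (s in seq_len(nrow(specs))) {
    spec <- specs[s, ]
    inGroup <- spec$sharedGroup > 0L
    gcol <- if (inGroup) match(as.character(spec$sharedGroup),
                               colnames(G)) else 1L
    g <- if (inGroup) G[, gcol] else rep(1, n)
    ts_ <- numeric(0)
    for (i in seq_len(n)) {
      gcat <- .maintGain(spec, trials, i)
      th <- lfpTruth$thetaPhase[i, ]
      env <- lfpTruth$gammaEnv[i, ]
      hi <- env > median(env)
      bg <- if (is.null(spec$betaGamma)) 0 else spec$betaGamma
      lam <- spec$baseRate * gcat *
        exp(spec$kappaVm * cos(th - spec$phasePref) +
            (spec$betaInt * cos(th) + bg) * hi) * g[i]
      if (inGroup) lam <- lam * Gslow[i, gcol, ]
      over <- lam > config$maxRate
      nCapped <- nCapped + sum(over & maintIdx)
      lam <- pmin(lam, config$maxRate)
      p <- lam[maintIdx] / fs
      hit <- which(runif(sum(maintIdx)) < p)
      tt <- trials$maintenance_onset[i] + tgrid[maintIdx][hit] +
        runif(length(hit), 0, 1 / fs)
      # piecewise-homogeneous segments outside the maintenance grid
      segs <- .trialSegments(trials[i, ], spec)
      for (sg in segs) {
        rate <- sg$rate * g[i]
        nev <- rpois(1L, rate * (sg$to - sg$from))
        if (nev > 0L) tt <- c(tt, runif(nev, sg$from, sg$to))
      }
      ts_ <- c(ts_, tt)
    }
    units[[spec$unit_id]] <- SpikeTrain(spec$unit_id, spec$region,
                                        spec$channel_id, sort(ts_))
  }
  gt <- data.frame(
    unit_id = specs$unit_id,
    tuned = apply(specs[, paste0("gain", 1:5)], 1L, function(x)
      max(x) > min(x)),
    preferredCategory = apply(specs[, paste0("gain", 1:5)], 1L, which.max),
    locked = specs$kappaVm > 0,
    pacInteracting = specs$betaInt > 0,
    kappaVm = specs$kappaVm, betaInt = specs$betaInt,
    sharedGroup = specs$sharedGroup)
  list(units = units, groundTruth = gt, sharedGain = G, nCapped = nCapped)
}

# homogeneous-rate segments of one trial outside the maintenance epoch grid
.trialSegments <- function(tr, spec) {
  segs <- list()
  add <- function(from, to, rate) {
    if (to > from) segs[[length(segs) + 1L]] <<- list(from = from, to = to,
                                                      rate = rate)
    segs
  }
  maintEpochStart <- tr$maintenance_onset - 0.5
  cur <- tr$trial_start
  for (k in seq_len(tr$load)) {
    on <- tr[[paste0("picture_onset", k)]]
    segs <- add(cur, min(on, maintEpochStart), spec$baseRate)
    gk <- spec[[paste0("gain", tr[[paste0("cat", k)]])]]
    segs <- add(on, min(on + 2, maintEpochStart), spec$baseRate * gk)
    cur <- on + 2
  }
  segs <- add(cur, maintEpochStart, spec$baseRate)
  # between end of maintenance analysis window and probe, then probe period
  segs <- add(tr$maintenance_onset + 2.5, tr$probe_onset, spec$baseRate)
  gp <- spec[[paste0("gain", tr$probe_category)]]
  segs <- add(tr$probe_onset, tr$probe_onset + 1, spec$baseRate * gp)
  segs
}

#' Simulate a full session with ground truth
#'
#' Composes [simulateTrialTable()], [simulateLfp()] (per channel) and
#' [simulateSpikes()] under the configured seed; with a fixed seed the
#' session is bit-identical across calls.
#'
#' @param config a `pacwmConfig` (default `syntheticConfig()`).
#' @return A list with `session` ([Session-class]) and `truth` (per-channel
#'   LFP ground truth, unit labels, shared gains, trial PAC depths).
#' @export
simulateSession <- function(config = syntheticConfig()) {
  set.seed(config$seed)
  trials <- simulateTrialTable(config)
  lfp <- list(); truthCh <- list()
  for (c_ in seq_len(config$nChannels)) {
    id <- sprintf("ch%d", c_)
    sim <- simulateLfp(config, trials, id)
    lfp[[id]] <- sim$epochs
    truthCh[[id]] <- sim$truth
  }
  sp <- simulateSpikes(config, trials, truthCh[[1]])
  kap <- truthCh[[1]]$kappaTrial
  if (config$rtModel$pacSlope != 0) {
    # regenerate RTs with the realised trial-wise PAC depths
    rtm <- config$rtModel
    rt <- rtm$intercept + rtm$loadEffect * (trials$load == 3L) +
      rtm$pacSlope * as.vector(scale(kap)) + rnorm(nrow(trials), 0, rtm$sd)
    trials$rt <- pmax(rtm$minRt, rt)
  }
  sess <- Session(trials, lfp, sp$units,
                  metadata = list(generator = "pacwm::simulateSession",
                                  seed = config$seed))
  list(session = sess,
       truth = list(lfp = truthCh, units = sp$groundTruth,
                    sharedGain = sp$sharedGain, kappaTrial = kap,
                    nCapped = sp$nCapped))
}

#' Two-neuron signal/noise geometry construction
#'
#' One neuron tuned (a mean offset added for the second category), one
#' untuned; both receive independent Gaussian noise and, per trial, a common
#' Gaussian offset (the shared noise) that creates noise correlations along
#' the (1,1) diagonal. 200 trials per category by default. The private noise
#' of the tuned neuron is slightly larger by default so the noise axis of the
#' correlation-removed control is well defined.
#'
#' @param nTrialsPerCat trials per category.
#' @param offset category-mean offset of the tuned neuron.
#' @param noiseSd private noise s.d. (length 2 or scalar).
#' @param sharedSd s.d. of the shared (correlated) noise.
#' @return A list with `rates` ((2 * nTrialsPerCat) x 2 matrix) and
#'   `labels`.
#' @export
simulateTwoNeuronGeometry <- function(nTrialsPerCat = 200L, offset = 2,
                                      noiseSd = c(1.2, 1), sharedSd = 1.5) {
  noiseSd <- rep_len(noiseSd, 2L)
  n <- 2L * nTrialsPerCat
  labels <- factor(rep(c("A", "B"), each = nTrialsPerCat))
  shared <- rnorm(n, 0, sharedSd)
  n1 <- offset * (labels == "B") + rnorm(n, 0, noiseSd[1]) + shared
  n2 <- rnorm(n, 0, noiseSd[2]) + shared
  list(rates = cbind(n1 = n1, n2 = n2), labels = labels)
}

#' Maintenance-period spike counts per trial and unit
#'
#' Convenience extraction of the trial x unit count matrix used by the
#' decoding analyses.
#'
#' @param session a [Session-class].
#' @param window count window relative to maintenance onset.
#' @param trials logical mask of trials (default: correct load-1 trials).
#' @return A list with `counts` (trials x units), `labels` (maintained
#'   category, load-1 trials) and `trialIndex`.
#' @export
maintenanceCounts <- function(session, window = c(0, 2.5), trials = NULL) {
  tr <- session@trials
  if (is.null(trials)) trials <- tr$correct & tr$load == 1L
  idx <- which(trials)
  counts <- vapply(session@units, function(u) {
    st <- spikesByTrial(u@timestamps, tr$maintenance_onset[idx],
                        window)$times
    lengths(st)
  }, integer(length(idx)))
  list(counts = counts, labels = tr$cat1[idx], trialIndex = idx)
}
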