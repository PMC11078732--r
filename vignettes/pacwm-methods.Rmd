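---
title: "Theta-gamma coupling and population geometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theta-gamma coupling and population geometry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements: the
models and statistics, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the choices we made where the design was genuinely open.

## The scientific setting

During the maintenance period of a working-memory task, hippocampal local
field potentials (LFPs) show theta-band (3-7 Hz) oscillations whose phase
modulates the amplitude of high-gamma (70-140 Hz) activity - phase-amplitude
coupling (PAC). The package quantifies that coupling, asks which single
neurons follow it, and asks what the co-fluctuations of such neurons do to
the information a population carries about the item held in memory. The unit
of analysis is a `Session`: a trial table (140 trials, 70 at memory load 1
and 70 at load 3, five stimulus categories, all analyses of maintenance
activity in the 2.5-s window starting at maintenance onset), epoched
microwire LFPs, and sorted spike trains.

## PAC: modulation index with trial-shuffled surrogates

For a phase band and an amplitude band, each trial is band-pass filtered
(zero-phase FIR) over a padded window (0.5 s on each side), the analytic
signal is taken, and the trial is trimmed to [0, 2.5) s so filter edge
artifacts never enter the analysis. Phase uses the cosine convention: 0 rad
at the oscillation peak. Phases and amplitudes are concatenated across trials
and the modulation index (MI) is the normalised entropy deficit of the mean
amplitude per 18-bin phase histogram:

MI = (log N - H(p)) / log N,   p_j = <A | phi in bin j> / sum_k <A | bin k>.

MI is 0 for a flat profile, 1 when all amplitude sits in one bin, and is
invariant to rescaling of the amplitude stream. Raw MI is biased by trial
count, spectral slope and non-stationarity, so it is z-scored against 200
surrogates in which the phase stream of each trial is paired with the
amplitude stream of a *different* trial. We use random derangements rather
than unrestricted permutations so no trial is ever paired with itself - a
strictly null surrogate. A normal distribution is fitted to the surrogate MIs
by moments, mirroring the usual practice. A channel counts as a PAC channel
when the mean z over theta x high-gamma comodulogram cells (and separately
theta x low-gamma) exceeds the standard-normal 95th percentile (1.64,
right-sided).

The comodulogram grid has phase centres 2-14 Hz in 2-Hz steps (2 Hz fixed
bandwidth) and amplitude centres 30-150 Hz in 5-Hz steps, with the amplitude
bandwidth equal to twice the phase centre frequency so that the modulation
side-bands of a coupled amplitude signal are retained. Because the phase grid
is even (2, 4, ..., 14 Hz) while theta is defined as 3-7 Hz, the "theta"
cells of the band averages are those with centres 4 and 6 Hz; this is a
deliberate reading of an ambiguity and is fixed throughout.

Single-trial PAC is the raw MI computed within one trial's 2.5-s window. It
is left un-normalised: per-trial surrogate standardisation is not described
for the trial-level analyses, per-trial derangements are impossible within a
single trial, and the mixed-model analyses that consume these values contain
channel-level intercepts that absorb per-channel offsets.

Two waveform controls accompany the PAC estimates. Cycle asymmetries
(peak-to-trough and rise-to-decay fractions per theta cycle, 0.5 for a
symmetric wave) guard against sawtooth-like waveshape masquerading as
coupling; time-reversal flips rise-decay about 0.5, which the tests exploit.
Nesting detection averages 500-ms raw-LFP windows centred on the
maximum-gamma time point within each occurrence of the preferred theta bin
and calls the channel nested when at least three local maxima fall within 45
ms (three cycles at 70 Hz) of the window centre.

## Spike-field coherence

Spike-field coherence is the mean vector length (MVL) of LFP phases at spike
times, |mean(exp(i*phi))|, computed per frequency of a bank of 40 complex
Morlet wavelets, centre frequencies log-spaced 2-150 Hz and cycle counts
log-spaced 3-10 (matched index-wise). Kernels are normalised to unit energy
so amplitude is comparable across frequencies before z-scoring; convolution
uses reflection padding and the result is trimmed to [0, 2.5) s. The
reconstruction quality control regresses the band-limited original on the
band-limited sum of wavelet components in sliding 500-ms windows (25-ms
step) and reports the R-squared grid.

MVL falls with spike count, so contrasted conditions are subsampled to equal
counts (500 repetitions, averaged); units need at least 50 spikes per
condition (10 for the preferred/non-preferred contrast, where non-preferred
spikes are scarce). The raw MVL is z-scored against 500 surrogates in which
every spike is re-drawn uniformly within its own trial's [0, 2.5) s window.
The jitter law is an open point in the source description ("random noise");
the uniform full-window law was chosen because it provably destroys locking
at every analysed frequency while preserving spike counts and trial
assignment. A local +/-0.5 s jitter is available through the arguments for
sensitivity analyses. Frequency-resolved contrasts between conditions use
cluster-based permutation statistics (below); families of such contrasts
(2 MTL areas x 3 frontal areas x 2 cell populations = 12 tests) use a
Bonferroni-adjusted cluster alpha.

## Category neurons and PAC neurons

Category cells are selected from encoding activity only: spikes are counted
200-1000 ms after every picture onset (encoding presentations and the
probe), a 1 x 5 permutation ANOVA (2000 permutations) tests for any category
dependence, and one-sided permutation t-tests compare the maximum-count
category against each of the other four; all tests must pass at p < 0.05.
The post-hoc tests are deliberately uncorrected across the four comparisons,
matching the stated procedure; the joint requirement already makes the
selection conservative. Area-level significance compares the observed count
of selected units to the 99th percentile of 500 whole-selection reruns under
category-label shuffles.

PAC neurons are units whose maintenance-period spike counts follow the
theta-phase x gamma-amplitude interaction of a same-region LFP. Theta phase
comes from the 3-7 Hz Hilbert transform; gamma amplitude from 7-cycle
wavelets at 70-140 Hz in 5-Hz steps, z-scored per frequency across all
trials before averaging (so the spectral power law cannot weight the average
toward low frequencies). Samples are split at the median gamma amplitude and
into ten 36-degree theta bins, giving 20 bins whose spike counts are
modelled by three Poisson GLMs (phase entered as cos and sin):

* model 1: count ~ cos + sin + gamma + (cos + sin) x gamma
* model 2: count ~ cos + sin + gamma (no interaction)
* model 3: count ~ cos + sin + (cos + sin) x gamma (no gamma main effect)

A unit is a PAC neuron when model 1 beats model 2 *and* model 3 by
likelihood-ratio tests at p < 0.01, Benjamini-Hochberg-corrected across the
unit's channel combinations, in either load. The model-3 comparison is the
guard against field-level PAC: when the LFP itself is strongly coupled, the
spikes falling in the two gamma halves necessarily differ in theta phase, so
an interaction can appear without any spike-gamma relationship - but in that
scenario the gamma main effect stays null, and the unit is rejected. The
selected channel for downstream analyses is the combination with the highest
model-1 R-squared, defined here as the squared correlation between observed
and fitted bin counts (the source leaves the definition open; a
deviance-based pseudo-R-squared is also returned). By default the GLMs carry
a log-occupancy exposure offset: bins are occupied for different amounts of
time exactly when the LFP has PAC, and without the offset that occupancy
imbalance can masquerade as a phase effect. The offset-free variant is one
argument away for comparison. The population-level null re-runs the entire
selection 200 times after re-pairing each unit's per-trial spike trains with
the LFP of a randomly chosen other trial.

A hypergeometric tail test checks whether PAC neurons and category neurons
overlap more than independent subpopulations of the same unit universe
would.

## Noise correlations, decoding, geometry

Noise correlations are computed per pair of same-region, different-channel
units as the Pearson correlation of 200-ms sliding counts (25-ms steps, 101
bins spanning the maintenance period) within each trial, averaged over
trials; the null shuffles trial pairings within condition 1000 times.
Correlations are *removed* by independently permuting each unit's trials
within each category - this preserves every unit's per-category count
distribution exactly (same multiset of rows) while destroying co-fluctuation,
so any decoding change is attributable to correlations rather than to
marginal statistics.

Category decoding uses correct load-1 trials only (load-3 maintenance mixes
three categories), trials subsampled to equal counts per category, z-scored
rates (fitted on training folds only - the source does not specify the
scaling protocol, and fitting on the full data would leak test statistics
into training), and a linear SVM with one-versus-one coding at fixed C = 1.
Greedy forward selection starts from the best single unit and repeatedly
adds the unit that most improves held-out accuracy, ties broken by lowest
unit index; accuracy curves are reported for intact and removed
correlations, and ablation utilities compare the curve maximum before and
after removing all PAC neurons or an equal number of random non-PAC units.
The greedy order is determined on the mean accuracy rather than per
repetition; recomputing the order inside every repetition would conflate
selection noise with the correlation effect being measured.

Geometry: for each binary learner of the one-versus-one set, the signal axis
is the unit normal of the SVM decision boundary and the noise axis is the
first principal component of the class-mean-centred training responses
(centring is the default; the uncentred variant is an argument). The angle
between the axes is folded to [0, 90] degrees and averaged across learners
and repetitions; projection variability is the s.d. of responses projected
on the signal axis, averaged across classes. Geometry is computed on raw
(mean-centred but not variance-scaled) rates by default: per-unit z-scoring
forces every unit's variance to 1, which erases exactly the variance
structure the noise axis is supposed to measure and, for tuned units,
absorbs signal variance into the normalisation. The decoder itself still
z-scores; only the axes are extracted in rate space.

The two-neuron construction used to illustrate the enhancing regime pairs a
tuned neuron (mean offset for one of two categories) with an untuned one,
adds independent Gaussian noise to each and a shared Gaussian offset to
both (200 trials per category). The private noise s.d. defaults to
c(1.2, 1.0): with exactly equal private noise the correlation-removed,
class-centred covariance is isotropic and the noise axis is undefined; the
slight asymmetry pins it without changing the phenomenon. In this
construction, shared noise rotates the noise axis away from the signal axis,
the SVM exploits the untuned neuron to cancel the shared noise, and removing
correlations therefore lowers accuracy, shrinks the angle, and inflates the
projection s.d. - the directions the acceptance tests assert.

Reaction-time analyses split correct trials at the median RT separately
within each load (ties to fast) and average the per-split correlations
across loads before contrasting fast versus slow.

## Permutation statistics

All condition contrasts use permutation tests: sign flips of paired
differences or label permutations, 10,000 permutations by default, p-values
with the (b+1)/(m+1) estimator so p is never 0 and always respects
p >= 1/(nPerm+1). Frequency-resolved contrasts use cluster-based correction:
contiguous frequencies with per-frequency t above the two-sided 5% quantile
form clusters scored by summed t, compared against the maximum cluster mass
under sign flips, at alpha 0.025 per one-sided cluster. Multiple-testing
control elsewhere is Benjamini-Hochberg (`p.adjust`). Trial-level models
(RT or firing rate against single-trial PAC with load as confounder and
random intercepts for channel nested in patient) delegate to `lme4`, with
Wald z p-values and an overdispersion flag for Poisson fits.

## The synthetic-session generator

The generator exists so that every stage can be tested against known ground
truth. Its defaults are the study conditions: 140 trials (70 per load), five
categories, 400 Hz sampling, a [-0.5, 3.0) s epoch around maintenance onset
analysed over [0, 2.5) s. The LFP of each trial is the sum of

* pink noise with spectral exponent 1.75 (the hippocampal log-log slope
  scale), RMS 10 uV;
* a 5 Hz theta cosine, 15 uV, random phase per trial;
* a band-limited (70-140 Hz) noise carrier - broadband, like real high
  gamma, so coupling is detectable across the band rather than at a line -
  whose envelope is gammaAmp x burst(t) x (1 + kappa_trial x cos(theta
  phase)).

`burst(t)` is a slow (10 Hz low-pass) log-normal fluctuation (sd 0.5). It
matters for identifiability: without it the gamma envelope is a
deterministic function of theta phase, the gamma median-split indicator
carries no information beyond phase, and no spike-count model could ever
attribute variance to a gamma main effect or interaction. Real gamma comes
in stochastic bursts; so does the generator's. The coupling depth defaults
to kappa = 0.8 in load 1 and 0.4 in load 3 - the direction of the load
effect to be recovered - with a trial-level jitter (sd 0.3 of the load
value) that gives single-trial PAC something real to track and lets the
optional RT model couple behaviour to coupling strength.

Spikes are Bernoulli-thinned at the LFP resolution from

rate = base x g_cat x exp(kappa_vm cos(theta - phi0) +
       (beta_int cos(theta) + beta_gamma) x 1[gamma envelope high]) x G,

with base 5 Hz (persistent maintenance activity), category gains (3 for a
tuned unit's preferred category), von-Mises-style locking kappa_vm, an
interaction gain beta_int (1.5 for PAC units) and a gamma main-effect gain
beta_gamma (0.8 for PAC units). The main-effect term is part of what a PAC
neuron *is* under the three-model selection: the selection demands that
model 1 beat the no-gamma model 3, so a unit whose rate contained only the
interaction term would be generated by model 3 itself and correctly rejected
by the guard. Ground-truth PAC units therefore fire more during gamma bursts
as well as shifting their phase preference with them. Encoding-period firing
is piecewise homogeneous at base x gain(category shown); the generator does
not model encoding dynamics beyond these rate steps.

The shared gain G has a trial-constant log-normal component and a slow
(below 1 Hz) within-trial log-normal component, both with log-s.d.
`sharedGainSd` (default 0.2) and shared by all units of a group. Two
components are needed because the package measures correlations two ways:
across trials (count correlations, decoding) - driven by the trial-constant
part - and across time bins within a trial (the 101-bin noise-correlation
statistic) - which a trial-constant gain cannot affect and the slow
component drives.

What the generator does not emulate: biophysics (no conductances or cell
types), inter-ictal artifacts (cleaning is tested on constructed artifacts
instead), electrode drift, cross-frequency phase-phase coupling, and any
encoding-period temporal structure beyond rate steps. Passing tests
therefore demonstrate that the estimators recover what they claim from
signals with realistic first- and second-order structure - not that real
hippocampal data satisfy the generator's assumptions.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses symmetric Hamming-windowed-sinc FIR kernels
  applied by centred convolution with reflection padding - exactly zero
  phase for a Type-I FIR. Transition width follows
  min(max(0.25 f_edge, 2 Hz), f_edge), additionally capped by the stop-band
  width for notches so the 1-Hz line-noise stops stay narrow.
* The Hilbert transform is the standard FFT construction of the analytic
  signal.
* Sample windows are half-open everywhere ([start, end)); trial-relative
  time 0 is maintenance onset; a 3.5-s epoch at 400 Hz is always 1400
  samples and the 2.5-s analysis window 1000 samples.
* Surrogate MIs reuse a precomputed (bin x phase-trial x amplitude-trial)
  sum tensor, making each surrogate O(bins x trials); a unit test asserts
  exact agreement with the naive concatenated computation.
* Empty phase bins raise an error naming the bin (full-session streams never
  produce them; single short trials can, and the single-trial wrapper maps
  that error to NA for the affected trial).
* Degenerate surrogate distributions (sd 0), zero-variance channels,
  all-constant trials, empty units and rank-deficient geometry inputs are
  either errors naming the object or flagged-and-skipped cases, never silent.
* Random derangements are drawn by rejection; for 10 or more trials the
  acceptance probability is ~1/e per draw.
* Greedy ties break toward the lowest unit index; `which.max` makes this
  deterministic.

## Problem sizes in the tests

The test-suite simulations are sized for a desk machine: 16-trial sessions
for plumbing tests, 30-140 trials for recovery tests, 100-200 surrogates
where calibration is measured (400 channels for the z-MI false-positive
rate, where the binomial error at 200 would be a third of the acceptance
band's width), 50 decoding repetitions and 5-8 synthetic ensembles in the
acceptance script. These sizes are the package's choices for fast,
reproducible verification; all defaults inside the functions remain at the
full values described above.

## Known limitations

* The NWB reader for the archived dataset is declared but not implemented;
  sessions enter through the CSV/JSON fixture layout or the generator.
* Single-trial MI values are raw and should be compared only within channel,
  which is how the mixed models use them.
* The cluster permutation operates over frequencies only (the analyses here
  never cluster over time).
* The Poisson GLM R-squared is a definition choice; both the correlation
  and deviance variants are reported so users can check sensitivity.
* Artifact screening replaces the source's manual-inspection step with the
  deterministic rules plus a machine-readable report; borderline epileptic
  activity that a reviewer would catch by eye is out of scope.
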