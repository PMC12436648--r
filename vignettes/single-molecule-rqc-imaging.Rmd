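---
title: "Measuring protein recruitment to single mRNAs: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring protein recruitment to single mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smtrack)
```

# What this package measures

smtrack analyzes live-cell single-molecule imaging experiments in which
mRNAs are tethered to the plasma membrane, imaged by TIRF microscopy,
and scored for binding of a fluorescently tagged protein — the
experimental design used to watch the ribosome-quality-control ligase
ZNF598 engage translating reporter mRNAs. The pipeline covers five
measurements:

1. **Engagement fractions** — the fraction of mRNAs per cell showing at
   least one qualifying colocalization with the tagged protein during a
   movie (the calibration readout for reporters carrying 0/1/3/12
   binding sites, and the recruitment readout for translating
   reporters).
2. **Residence (on) times** — dwell times of single binders on an mRNA,
   segmented from intensity traces.
3. **Stoichiometries** — bound-spot intensities normalized by the mean
   single-binder intensity of the one-binding-site calibration
   construct.
4. **Ribosome-runoff clearance** — per-mRNA times for the
   translation-site (SunTag) signal to fall below 10% of its maximum
   after a harringtonine-type initiation block, summarized as
   Kaplan–Meier survival curves with Greenwood confidence bands.
5. **Nascent-peptide counts (NAP)** — in fixed cells, translation-site
   intensity divided by the same cell's mean single-protein intensity
   (smFISH-IF).

Because raw movies from such experiments are large and rarely
redistributable, the package ships a synthetic-data generator whose
defaults *are* the study conditions: every stage can be validated
against exact ground truth, and the pipeline's headline numbers are
parameter-recovery exercises in which the published values are the
generator's inputs.

# The synthetic generator

## Binding kinetics

A binding site alternates between unbound and bound states as a
two-state continuous-time Markov chain: binding initiates at rate
$k_{\mathrm{on}}$ (per second, per site) and on-times are exponential
with mean $\tau_{\mathrm{on}}$. The single-site calibration preset uses
$\tau_{\mathrm{on}} = 3.6$ s, sampled every 2 s for 5 min — conditions
under which an episode often spans only one or two frames, which is
exactly why the estimator section below matters.

Engagement — does this mRNA ever show a *detectable* colocalization? —
is handled in two ways:

* **Calibrated kinetics (1x preset).** Every mRNA runs the renewal
  kinetics, and $k_{\mathrm{on}}$ is solved (by an exact dynamic
  program on the frame-sampled chain, `engagement_probability()` /
  `calibrate_kon()`) so that the probability of at least one run of 5
  consecutive bound frames in a 151-frame movie equals the preset's
  engagement probability (0.5). This keeps episode durations exactly
  exponential — no conditioning — so dwell-time recovery stays
  unbiased. The cost is a softer reading of "engaged": non-engaged
  mRNAs still show sub-threshold flickers, and the engaged flag in the
  ground truth is defined as "shows a qualifying run".
* **Gated engagement (3x/12x and ZNF598-type presets).** A Bernoulli
  gate decides whether the mRNA binds at all; gated-off mRNAs draw no
  episodes, gated-on mRNAs are guaranteed at least one qualifying
  episode (multi-site presets by rejection; recruitment presets by
  drawing the transient duration as $t_q + \mathrm{Exp}(\mu - t_q)$
  with $t_q = 10$ s the qualification time and $\mu = 3.5$ min the
  total mean). These cohorts recover their gate exactly but their
  duration distributions are conditioned, so they are not used for
  dwell-time recovery.

ZNF598-type recruitment episodes are a mixture: persistent (outlasting
the 5-min window, probability 0.5) and transient (mean 3.5 min).

## Motion, rendering and noise

Tethered mRNAs wander as a discrete Ornstein–Uhlenbeck process around
an anchor (stationary SD 0.6 px ≈ 100 nm at 160 nm/px, relaxation 10 s)
— confined enough to track, mobile enough to exercise the linker.
Movies are rendered through a pixel-integrated Gaussian PSF (σ = 1.3 px
laterally; separable Gaussian in z for 3D smFISH stacks), with Poisson
photon noise plus Gaussian read noise on a constant background. The
paper-equivalent calibration (160 nm pixels, 2-s frames steady state,
10-s frames runoff) is the default `render_config()`. No photon budget
is reported for the original experiments, so the defaults here are
declared, not inferred: 300 photons per intensity unit for live-cell
movies (10:1 peak SNR territory) and 2000 photons per single protein
for smFISH-IF, where antibody-amplified spots are bright and a dim
setting would put single proteins below any defensible detection
threshold.

Trace-level simulation (`simulate_binding_cohort()`,
`cohort_to_tracks()`) bypasses rendering for cohort-scale statistics;
rendering (`render_movie()`, `simulate_smfish_field()`) is used to
validate the detection stage itself.

What the generator does **not** emulate: dye blinking and
photobleaching (the underlying experiments showed dwell times
insensitive to an eightfold laser-power range, so photophysics is out
of scope), cell-shaped masks, stage drift, chromatic offsets, and
autofluorescent structure in the background. Passing tests therefore
demonstrate correctness of the estimators under the stated noise model,
not robustness to every artifact of real microscopes.

# Estimators

## Dwell times at a finite frame rate

At a 2-s frame interval, an exponential on-time with mean 3.6 s is
severely under-sampled: ~43% of episodes cover no sample point at all,
and the mean *detected* episode length is about 4.7 s. Averaging
detected durations therefore cannot recover the true mean; this is a
property of the sampling, not of any particular detector.
`residence_time_stats()` offers four policies:

* `mean` — the arithmetic mean of uncensored durations. Reported for
  transparency; biased as above.
* `exp_mle` — inverts the geometric law of run lengths: given the
  binder is seen on one frame, it is seen on the next with probability
  $q = e^{-\Delta t/\tau}$, so $\hat\tau = -\Delta t / \log(1 - 1/\bar
  n)$ with $\bar n$ the mean frames per run. Corrects under-sampling
  but not re-binding.
* `markov` — treats the sampled trace as the exact discretization of
  the two-state chain: transition counts give the sampled transition
  matrix, whose matrix logarithm returns $k_{\mathrm{on}}$ and
  $k_{\mathrm{off}} = 1/\tau$. This additionally corrects for
  unbind-and-rebind events that fall between frames and merge adjacent
  runs (with the calibrated 1x preset these merges alone bias
  `exp_mle` by ~4%). This is the estimator the steady-state pipeline
  reports.
* `exp_censored` — for long dwells truncated by the movie: total
  observed exposure divided by the number of observed terminations
  (right-censoring-aware exponential MLE), with an optional known
  lower bound subtracted and restored. Used for the minutes-scale
  recruitment dwells, where a naive average over tracks that end
  within a 5-min window is bounded near 2.5 min regardless of the true
  mean and is therefore not a usable statistic.

## Change-point segmentation

Traces are segmented by recursive binary splitting on a two-sample
t-type statistic with two numerical choices that matter:

* The noise SD is estimated once per trace from the median absolute
  first difference (divided by $\sqrt 2$). Unlike the pooled SD of the
  two halves, this estimate is insensitive to the steps themselves — a
  pulse train otherwise inflates the variance estimate until nothing
  is significant.
* After the binary pass, each flat segment is scanned for the most
  significant sub-interval (all $O(n^2)$ intervals, Bonferroni
  corrected). A single split can never isolate a one- or two-frame
  dwell in the middle of a long quiet stretch — both half-means are
  diluted — so this pulse pass is what makes frame-resolution dwell
  recovery possible.

The significance budget `alpha` (default 0.01) is split between the
two passes; critical values use t quantiles so the estimated noise SD's
own uncertainty is absorbed. Noiseless traces split on any exact mean
difference, with the boundary placed at the largest one. Segments whose
mean exceeds `level_threshold` (default 0.5 binder units) become bound
states; the eight-second minimum bound duration (four frames at 2 s) is
applied for engagement counting but disabled when estimating dwell
times, which need every run.

## Colocalization rules

All reported thresholds are implemented verbatim and exercised at their
boundaries in the test suite: mRNA tracks shorter than 25 frames and
protein tracks shorter than 4 frames are discarded; linking two tracks
requires 4 frames of spatial overlap (2 in runoff/UV mode); a
colocalization event requires 5 consecutive within-radius frames (2 in
runoff/UV mode); cells need more than 15 mRNAs (calibration assays) or
more than 10 translating mRNAs (recruitment assays) to count. The
spatial radius (1.5 px ≈ 240 nm) replaces the original study's manual
overlap curation and is a configuration knob, not a reconstruction.

## Runoff survival

Clearance time is the interval from the translation-site maximum to the
first frame strictly below 10% of that maximum, after excluding
not-translating molecules (first-4-frame mean under 10% of max) and
molecules whose mRNA and translation-site losses coincide within 3
frames; signal persisting past the window is right-censored.
Kaplan–Meier curves carry Greenwood variance
$\mathrm{Var}(S) = S^2 \sum d_i / (n_i(n_i - d_i))$ with plain 95%
bounds clipped to [0, 1] (log–log available). Cohorts are compared by
the ratio of KM medians; the crossing is linearly interpolated by
default because at 10-s frames the step median is quantized to the
frame grid, which only adds noise to a ratio (the step version remains
available).

The baseline clearance-time distribution is lognormal with median 240 s
and log-SD 0.35 — chosen once so that roughly 90% of normal messages
clear within 10 min, matching the published behavior of the no-insert
reporter; the overexpression preset divides clearance times by 1.5. The
pre-ramp plateau hold is at most one frame: after an initiation block,
elongating ribosomes start leaving immediately, and a long hold would
separate the measured maximum from the ramp start that defines the true
clearance time.

## smFISH-IF quantification

3D stacks are LoG-filtered, candidate maxima are fit with
pixel-integrated 3D Gaussians, and protein spots within 2 px laterally
and 1 plane axially of a detected mRNA become translation sites. Single
proteins are protein spots outside a 3-fitted-sigma ellipsoid around
every translation site; cells need at least 5 singles for a usable unit
mean, and NAP counts divide each site's intensity by its *own* cell's
unit mean, making the count exactly invariant to global intensity
rescaling.

# Default problem sizes

The shipped analyses use cohort sizes at which the estimators' standard
errors are small relative to the effects of interest while a full run
stays interactive on a laptop: 2000 traces for dwell recovery (~16,000
episodes), 30 cells × 30 mRNAs for engagement fractions, 150 molecules
per runoff cohort, 300 for the damaged-subpopulation assay, and 200
translation sites across four rendered fields for NAP recovery. All are
arguments, not constants.

# Known limitations

* The dwell-time estimators assume a single dominant binder species
  with exponential on-times; multi-exponential mixtures will be
  reported as an effective mean.
* Binary-plus-pulse segmentation is not a global optimum search; traces
  with dense steps of many distinct levels (high-stoichiometry
  recruitment) are segmented greedily.
* The tracker links frame pairs optimally but does not propagate a
  motion model; it is matched to tethered, slowly wandering molecules,
  not to fast directed transport.
* Cell masks are inputs (rectangular strips in the generator); no cell
  segmentation is attempted.
* The generator's engagement flag for the calibrated 1x preset is
  defined through the 5-consecutive-frame rule; analyses using a
  different event rule should use the gated presets.
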