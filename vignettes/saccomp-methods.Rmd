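---
title: "Models and methods behind saccomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind saccomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

When a saccade lands off target, the brain needs an estimate of the motor
error — the difference between where the eyes were *meant* to go and where
they actually went — to drive a corrective (secondary) saccade and to
calibrate future movements. In posterior parietal cortex two neuron classes
carry the two halves of that comparison:

* **PPS neurons** (persistent pre- and post-saccadic response) ramp up
  before the saccade and keep firing after it. Their peri-saccadic activity
  is direction selective but *uncorrelated* with the trial-to-trial jitter
  of the landing position: they encode the intended end position (the
  target).
* **LPS neurons** (late post-saccadic response) are silent until roughly
  70 ms after the saccade ends, then fire at a level positively correlated
  with the *actual* horizontal end position — the timing and tuning of an
  extraocular proprioceptive signal.

Once the LPS signal arrives, the late activity of the PPS population
(150–350 ms after saccade end) stops being flat in end position and becomes
V-shaped: lowest for saccades landing on target, higher the farther the eye
landed from it, on both the undershoot and the overshoot side. That
post-subtraction activity behaves like `|LPS − PPS|` in normalized units,
correlates with the magnitude of the saccadic error, and predicts whether a
corrective saccade follows. `saccomp` implements the full analysis chain
that establishes those facts, together with a synthetic-session generator
with known ground truth so that every estimator can be validated.

## The synthetic session generator

Because the original recordings are not publicly deposited, the package
ships a generator (`generator_config()`, `generate_session()`) whose
defaults encode the study conditions:

| parameter | default | anchor |
|---|---|---|
| target eccentricity | 10 deg | task geometry |
| end-position mean / SD | 9.6615 / 0.4894 deg | reported behavioural moments |
| PPS decay time | N(74.8, 33.1^2) ms after saccade end | reported population statistics |
| LPS rise time | N(70.9, 31.3^2) ms after saccade end | reported population statistics |
| secondary-saccade latency | ~154 ms after the primary saccade | reported mean latency |
| overall secondary-saccade rate | ~0.25 | reported 1009 of 4090 trials |
| trials per direction | 60 | typical per-neuron trial counts (>30 required) |

Eye traces are sampled at 1 kHz. The primary saccade follows a
minimum-jerk displacement profile `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`
with duration drawn uniformly from 25–60 ms, so its peak speed has the
closed form `1.875 * amplitude / duration` (over 200 deg/s for a 10-degree
saccade — comfortably above the 30 deg/s detection threshold). White
position noise (SD 0.01 deg) and a small zero-mean post-saccadic drift are
added. Corrective saccades are minimum-jerk movements back toward the
target, launched 110–300 ms after the primary saccade end.

Spike trains are inhomogeneous-Poisson samples (thinning, with the
profile's analytic maximum as the dominating rate; an independent
time-rescaling sampler is used as the test oracle). The PPS rate profile is
baseline (8 spikes/s) until 200 ms before saccade onset, ramps linearly to
its peak (40 spikes/s) at the neuron's true decay time, and decays
exponentially (time constant 45 ms) thereafter; this follows the described
temporal profile, where activity climbs until shortly after the saccade and
then turns over, rather than holding a flat plateau. The LPS profile is
baseline until the true rise time, then ramps within 20 ms to a sustained
level `40 + 8 * (end position - 10)` spikes/s. Null-direction trials stay
at baseline for both classes.

### The latent error signal

The post-subtraction behaviour is generated through a single latent
per-trial error signal

```
e_t = |end position - target| + N(0, 0.25 deg)
```

— a noisy but conditionally unbiased internal estimate of the error (it may
dip below zero; rates are floored at zero inside the profile and the
probability below is clamped). It (a) adds `pps_error_gain * e_t` (default
4 (spikes/s)/deg, with 40 ms raised-cosine edges) to every PPS neuron's
rate inside the 150–350 ms post-saccadic epoch, and (b) sets the
corrective-saccade probability to `0.015 + 0.45 * e_t` (clamped to [0, 1]).
The *shared* noise term is essential: it is what makes trials with a
corrective saccade carry higher post-subtraction activity even at matched
end positions — the comparison-drives-correction observation. A generator
in which the secondary decision depended on the geometric error alone would
show almost no within-bin activity difference. (An earlier clipped variant,
`max(0, ...)`, put a ~0.1 deg floor under the on-target trials that
reference subtraction turned into a systematic offset between the observed
and predicted error curves.)

The gains deserve comment, since the recordings report only normalized
correlations, never rate slopes:

* `lps_position_gain = 8` puts the emulated single-trial correlation
  between LPS activity and end position in the reported range
  (population mean r ≈ 0.10–0.15 in the [25, 125) ms window) *and* makes
  it reliably detectable with ~24 neurons. Weaker gains produce whole
  simulated populations in which the reported effect would be
  statistically invisible.
* `pps_error_gain = 4` is set so that the *measured epoch slopes* match:
  the LPS window expresses only ~39% of its gain per degree (the rise
  latency and ramp occupy the window's first half on average, and the
  detected saccade offset sits a few ms before the true movement end,
  shifting the window into the rise) while the PPS post-subtraction window
  expresses ~80% (the cosine edges). Matching measured slopes is exactly
  the subtraction-model consistency the analysis tests, and it lands the
  emulated post-subtraction error correlation at r ≈ 0.15, the scale
  reported.
* the PPS decay time constant (45 ms) is calibrated so that the population
  middle-point gap — LPS activity rising 25 ms before PPS activity starts
  decaying — matches the reported index.

Randomness is split hierarchically: each trial's behaviour and each
(neuron, trial) spike train gets its own substream keyed by the session
seed, so adding neurons never perturbs existing trials and an identical
seed reproduces a session bit for bit.

### What the generator does not emulate

Rate profiles are piecewise-smooth idealizations: no bursting, no
history dependence (the Poisson assumption), no microsaccades or blinks in
the eye traces, no correlated noise across neurons beyond the shared error
signal, and no visual transients. Passing tests therefore show that the
estimators recover the structure the analysis assumes; they cannot show
robustness to everything real recordings contain.

## Saccade detection and trial screening

Eye speed is the magnitude of the 2-D central difference of the position
trace after a 5 ms boxcar smooth (both exposed as arguments; the
literature rarely states its differentiator, so the choice is documented
rather than hidden). A primary saccade starts at the first sample after
fixation-point offset exceeding 30 deg/s and ends at the first sample
after the speed peak below 10% of that peak. The end point is the mean eye
position over 0–20 ms after the offset. Trials are included when the
duration is 10–100 ms (inclusive), the end point is within a 5-degree
window centred on the target (square by default, circular as an option),
the amplitude exceeds 4 degrees (strict) and the latency is under 500 ms
(strict). Secondary saccades use an 8 deg/s onset threshold, duration
> 5 ms, amplitude > 0.2 deg, and onset at least 100 ms after the primary
saccade offset; all qualifying events count, whatever their direction.
Template-matching criteria sometimes used alongside velocity thresholds
are not implemented. Both detectors are validated sample-for-sample
against independent brute-force threshold scans.

All analysis windows are half-open `[a, b)` in ms, so boundary spikes are
counted exactly once. Left-direction trials are mapped into *motor
coordinates* (sign-flipped so the preferred target is +10 deg) before any
pooling.

## Spike density and epochs

Spike densities are sums of unit-area Gaussians (sigma = 5 ms) evaluated
exactly on the 1 ms grid. Epoch rates are half-open window counts divided
by the window length. Single-neuron activity is normalized by *division*
by the neuron's baseline rate (100–500 ms after fixation onset), with a
floor of 1 spike/s so near-silent baselines cannot explode the ratio; the
classification rules use the [0, 500) baseline window, as the two uses are
stated with different windows. Population traces are pointwise means with
a normal-approximation 95% CI.

## Change-point estimation

Decay and rise times are estimated by the exponential-scan procedure: find
the peak of the trial-averaged density (20 ms moving window, 1 ms step)
within ±250 ms of saccade completion; take the end point (the minimum after
the peak, or the peak itself for a rise); delimit a fluctuation period from
the peak (trough) to the point *after which* the activity stays below
(above) the bound — peak − 2 STE or 80% of peak, whichever is crossed
first; fit `y = A1 * exp(x / A2) + A3` by Levenberg–Marquardt from every
1 ms candidate start inside that period to the end point; and report the
start of the best fit. Numerical choices that the procedure's verbal
description leaves open, and how this implementation resolves them:

* **Sustained crossing.** A single noise dip on the plateau must not
  terminate the fluctuation period, or the true transition can fall
  outside the candidate range entirely; the boundary is therefore the
  first point from which the activity never returns above the bound
  before the end point.
* **Weighted residuals.** Poisson variance scales with rate, so an
  unweighted mean squared error rewards fits that simply exclude the
  noisy high-rate samples near the peak, biasing the scan late. Residuals
  are standardized by the across-trial SEM of the density (smoothed and
  floored) whenever per-trial data are available; noiseless traces fall
  back to the plain MSE.
* **Minimum-MSE start, earliest on ties.** The reported time is the start
  of the minimum-(weighted-)MSE fit; exact ties — which a noiseless planted
  transition produces for every start inside the pure-exponential segment —
  resolve to the earliest candidate. With the generator's peaked profiles
  this plain argmin is unbiased to within a few ms; softer profiles (long
  flat plateaus with slow decays) leave the start genuinely
  under-identified and the scan noisier, whatever the tie-break.
* **STE definitions.** For the decay bound, STE is the SEM of per-trial
  mean densities in the 20 ms peak window. For the rise bound, the trough
  window is itself a low-count extreme whose own SEM understates the
  baseline noise band, so the baseline-region SEM is used instead.
* Non-convergent candidate fits are skipped; candidates leaving fewer than
  8 samples to the end point are not fitted.

On simulated sessions at study scale (60 trials per direction, default
rates) the estimators recover planted noiseless transitions within ±2 ms
and generative change times with per-neuron RMSE around 20 ms (decay,
whose shallow apex at these firing rates is genuinely hard to pin down) and
~12 ms (rise), with population means within a few ms of the generative
means — the precision claims the acceptance suite measures, at the problem
sizes stated there (89 PPS and 27 LPS neurons).

## Classification

`classify_neurons()` applies the published multi-criterion rules.
Directional rules ("significantly greater") are tested one-sided; equality
rules ("not significantly different", LPS rules 1–2) are two-sided at
p > 0.05. Rate-vs-baseline comparisons are paired across trials (t-test,
or signed-rank where a rank test is named); preferred-vs-null comparisons
are rank-sum tests on independent trial sets. The 20 ms pre-saccadic bins
tile [−200, 0) before saccade onset; the 50 ms post-saccadic bins are not
anchored by the published description, and tiling only [0, 200) would fail
every late riser by construction, so the rule passes if either the
[0, 200) or the [100, 300) tiling yields ≥ 2 significant bins. Change
points are estimated lazily — only when the cheaper statistical rules
leave the class attainable. A neuron passing both rule sets (pathological
input) is labelled PPS and flagged.

One property of the published rules is worth stating plainly: the LPS
definition contains three *equality* screens, each of which falsely rejects
a true LPS neuron 5% of the time by construction. Even a perfect pipeline
therefore misses ~10–14% of true LPS neurons; together with the 35 ms
rise-time boundary this caps LPS sensitivity around 85–90%. That ceiling
is a property of the rules, not of the estimators, and the acceptance
suite measures it honestly rather than relaxing the rules.

## The comparator analyses

Trials are pooled across neurons on each neuron's preferred side, in motor
coordinates. End positions are binned into equal-width bins spanning the
mean ± 3 SD (16 bins for PPS pools, 6 for LPS and corrective-saccade
pools); under-filled bins are merged with their nearest neighbour, except
when a fixed grid is shared between activities (as the subtraction model
requires), in which case under-filled bins are kept and simply carry no
mean. Reference normalization subtracts the mean activity of the bin
containing the target, so the on-target condition maps to zero by
construction.

Single-trial correlations are Pearson r per neuron (≥ 30 preferred trials
required), followed by a one-sample t-test of the per-neuron r values
against zero. The published population tests are labelled "paired
t-test"; a one-sample test of r against zero is the only coherent reading
and is what is implemented. Correlations are computed on raw r values, not
Fisher-z, to match the reported mean-r statistics.

The subtraction model fits weighted least-squares lines to the
reference-normalized LPS post-saccadic and PPS perisaccadic bin means,
predicts the error signal as their absolute difference on the bin centers,
and reports the RMS deviation from the observed post-subtraction bin means
on the same grid, plus piecewise (undershoot/overshoot) fits of the
observed activity split at the predicted vertex. The sliding-window
analysis computes the per-window (100 ms, 10 ms steps over [0, 450] ms
after saccade end) population correlation between window rates and
absolute error.

Corrective-saccade statistics reuse the same bin edges so probability and
activity are computed on identical partitions; per-bin with-vs-without
comparisons are rank-sum tests, skipped when a subgroup is empty.

## Validation design

The acceptance analyses select the PPS/LPS populations by their generative
arm (the classifier is itself validated separately, on a 200-neuron
population); preferred directions are always estimated from the data. The
problem sizes — 500 trials for detector-oracle equivalence, 89 + 27
neurons for change-point recovery, 200 neurons for classification, ~100
neurons × 160 trials for the comparator, 100 seeded replicates for the
coupling sign — were chosen to make the checked quantities statistically
stable. `scripts/acceptance.R` regenerates the headline numbers from
scratch for any seed.

## Known limitations

* Decay-time estimates carry ~20 ms per-neuron RMSE at study-scale firing
  rates; population means are accurate to a few ms, single neurons are not.
* The classification rules' equality screens impose the sensitivity
  ceiling discussed above.
* The generator's 2-D hook exists (vertical traces, oblique targets are
  representable) but all analyses and validation target horizontal trials.
* No blink/artifact rejection and no adaptive-kernel rate estimation; the
  pipeline assumes clean traces and stationary baselines.
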