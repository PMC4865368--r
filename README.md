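# saccomp

Saccadic error comparator analysis for trial-structured spike recordings.

## What this package is for

During a delayed saccade task, posterior parietal cortex holds two
complementary spatial signals. Neurons with **p**ersistent pre- and
**p**ost-**s**accadic responses (PPS) fire around the saccade at a level
that tracks the *intended* end position — the target — and is indifferent
to the trial-to-trial jitter of where the eye actually lands. Neurons with
**l**ate **p**ost-**s**accadic responses (LPS) start firing ~70 ms after
the saccade ends, at a level positively correlated with the *actual*
horizontal end position (the timing of extraocular proprioception). Once
the LPS signal arrives, the late PPS activity (150–350 ms after saccade
end, the *post-subtraction* epoch) becomes V-shaped in end position —
lowest on target, rising with the miss on either side — as if the
population computed

    error ≈ | LPS − PPS |          (in baseline-normalized units)

and that post-subtraction activity predicts whether a corrective
(secondary) saccade follows.

`saccomp` implements the full analysis chain for researchers who want to
apply or scrutinise it: saccade detection from 1 kHz eye traces with the
published inclusion filters, Gaussian-kernel spike densities and epoch
rates, exponential-fit change-point estimation of decay/rise times, the
multi-criterion PPS/LPS classifier, end-position binning with reference
subtraction, the subtraction model, sliding-window error correlations, and
corrective-saccade statistics. Because the original recordings are not
deposited, the package also ships a fully parameterised synthetic-session
generator (minimum-jerk eye kinematics + inhomogeneous-Poisson spike
trains) with known ground truth, which is how every estimator here is
validated.

## A worked example

```r
library(saccomp)

cfg <- generator_config(n_pps_neurons = 20, n_lps_neurons = 12,
                        n_trials_per_direction = 60, rng_seed = 42)
gs <- generate_session(cfg)
session <- gs$session
session
#> <scs_session> synthetic_scs_seed42  task=SCS_horizontal  120 trials, 32 neurons @ 1000 Hz

trials <- detect_saccades(session)   # detection + inclusion filters
sprintf("included trials: %d of %d; corrective saccades on %.1f%%",
        sum(trials$passed), nrow(trials), 100 * mean(trials$has_secondary))
#> "included trials: 120 of 120; corrective saccades on 25.8%"

labels <- classify_neurons(session, trials)
table(labels$label)
#>     LPS neither     PPS
#>      11       3      18

# does late PPS activity track the magnitude of the saccadic error?
ep <- epoch_windows()
pps <- labels[labels$label == "PPS", ]
post <- activity_table(session, trials, pps,
                       ep$post_subtraction$window, ep$post_subtraction$align)
single_trial_correlation(
  data.frame(neuron_id = post$neuron_id, activity = post$activity,
             x = abs(post$x - 10)))
#> <correlation_result> 18 neurons, mean r = 0.1543 (p = 0.00113)
```

All 120 trials pass the inclusion filters (the generator emits clean
trials by design), about a quarter carry a corrective saccade, 29 of the
32 simulated neurons are recovered by the classifier (the misses are draws
rejected by the published rules' own equality screens and 35 ms
change-time boundary), and the post-subtraction PPS activity is positively
correlated with the absolute saccadic error on single trials (mean
r ≈ 0.15, population p ≈ 0.001) — the package's core finding, reproduced
end to end on synthetic ground truth.

The methods vignette (`vignettes/saccomp-methods.Rmd`) documents the
generative model, every numerical choice in the estimators, and the known
limitations.

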