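# hydrostatus

Noninvasive estimation of mild exercise-induced dehydration from wearable
sensors. `hydrostatus` implements a complete, testable pipeline for
classifying whether an athlete has lost ≥ 2% of their nude bodyweight to
unreplenished sweat, using only two signals that commercial wearables
already record: chest-strap heart rate (~1 Hz) and trunk pitch from an IMU
(100 Hz), captured while the athlete performs short scripted postural
movements (supine-to-stand tests, toe-touches, a "tired runner" pose).

The physiological basis is the orthostatic response: on transitioning to
standing, heart rate rises to compensate for reduced venous return, and
hypovolemia from dehydration amplifies that rise. The package turns each
postural repetition into a three-dimensional feature vector and classifies
it with a regularized linear model:

- **Features.** The heart-rate signal is smoothed with a trailing 4-s moving
  average. Each repetition's transition to standing is detected
  automatically as the peak of the trunk-pitch angular velocity
  (moving-average prefilter, central differences). The post-transition
  standing period of length *L* is split into three equal segments, and the
  features are the baseline-relative deltas
  *d&#7522; = mean HR in segment i − mean HR in the 10 s before the transition*
  (i = 1, 2, 3, in bpm). Referencing to the local pre-transition baseline
  removes between-person resting-HR differences and slow exercise-recovery
  drift.
- **Classifier.** L2-regularized logistic regression on standardized
  features: minimize Σ log(1 + e^(−y(w·x+b))) + ‖w‖²/(2C) with the
  intercept unpenalized. The strength C is chosen per training set by
  maximizing the pooled leave-one-participant-out cross-validation AUROC on
  a decade grid 10⁻³…10³.
- **Evaluation.** Leave-one-participant-out (LOPO): for each held-out
  participant the model is trained on everyone else and scored on the
  held-out post-exercise repetitions. AUROC is computed in its Mann–Whitney
  form (ties count ½) per participant and summarized as a mean with
  interquartile range, overall and per movement type.
- **Attribution.** Exact Shapley values over the 2³ feature coalitions, with
  the value function v(S) = held-out AUROC of a model refit on coalition S
  (v(∅) = 0.5, chance).

Because raw study recordings of this kind are generally not public, the
package includes a synthetic cohort generator (`simulate_cohort()`) that
emulates the full crossover protocol — two sessions (no-fluid vs
fluid-replaced), pre- and post-exercise batteries of 12 repetitions across
five movements, first-order orthostatic HR kinetics with
literature-anchored effect sizes (26 ± 12 bpm dehydrated vs 14 ± 8 bpm
euhydrated), exercise-recovery baseline drift, and sensor noise — so every
stage of the pipeline is testable end to end. A participant characteristics
table for a 20-person cohort ships as a plain-text fixture for the cohort
summary statistics.

## Worked example

```r
library(hydrostatus)

study <- simulate_cohort(n_participants = 20, seed = 1)
study
#> <synthetic_study> 20 participants, 80 battery recordings, 960 repetition windows (240 dehydrated), seed 1

dataset <- build_labeled_dataset(study)   # smooth, detect, segment, label
ev <- lopo_evaluate(dataset)
ev
#> Leave-one-participant-out evaluation (ALL)
#>   mean AUROC: 0.78 (IQR: 0.71, 0.86) across 20 participants

shapley_importance(dataset)
#> Shapley feature importance (value function: held-out AUROC; v(empty) = 0.5 (chance) )
#>  feature  mean    sd
#>       d1 0.074 0.028
#>       d2 0.100 0.025
#>       d3 0.109 0.041
#>   across 20 held-out participants
```

The mean AUROC of 0.78 says that for a typical held-out participant the
model ranks a random dehydrated repetition above a random euhydrated one
78% of the time — far from chance (0.5), using 30–60 s of standing after an
everyday movement. The Shapley ordering (segment 3 > segment 2 > segment 1)
reflects the first-order rise kinetics: with a ~20 s time constant, the
late-standing heart rate separates the hydration states most. Per-movement
summaries come from `lopo_by_movement(dataset)`, and the cohort table

```r
tab <- read_participant_table(
  system.file("extdata", "table1_participants.csv", package = "hydrostatus"))
summarize_cohort(tab)
#> Cohort of 20 participants
#>   Percent bodyweight lost: 2.0% +/- 0.3%
#>   M (n = 10): 75.4 +/- 9.9 kg pre, 73.9 +/- 9.7 kg post exercise; VO2max 53.4 +/- 2.10
#>   F (n = 10): 63.8 +/- 5.5 kg pre, 62.5 +/- 5.4 kg post exercise; VO2max 46.6 +/- 3.61
```

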