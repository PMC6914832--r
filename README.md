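# synergycube

Muscle-synergy posture classification and intermittent cube control from
surface EMG of a single muscle.

## What this is for

Modern multi-degree-of-freedom myoelectric prostheses need several
independent control signals. One candidate source is a single
multifunctional muscle: the biceps brachii participates in shoulder,
elbow and wrist/forearm action and is internally compartmentalized, so
its surface-EMG pattern across a handful of electrodes differs between
static arm postures. `synergycube` is a complete, scriptable desk model
of a control scheme built on that idea, for researchers studying
synergy-based prosthesis control:

1. **Envelopes** — five EMG channels are reduced to sliding-window RMS
   envelopes (250 ms window, 70 ms hop at 2000 Hz).
2. **Synergy extraction** — for every pair of static postures, the
   concatenated envelopes V (channels x frames) are factorized by
   non-negative matrix factorization, V ≈ W H (Lee–Seung multiplicative
   updates, squared Frobenius error), with 30 seeded restarts; the
   restart whose activation columns best separate the two postures by
   Rousseeuw's silhouette index, s(i) = (b(i) − a(i)) / max(a(i), b(i)),
   is kept.
3. **Classification** — an n-posture classifier is the round-robin
   ensemble of all n(n−1)/2 pairwise models (28 for n = 8, 10 for
   n = 5). Each model projects an incoming frame into its activation
   space by non-negative least squares and votes for the posture whose
   cluster-mean activation is nearer (minimum Euclidean distance);
   winner takes all.
4. **Control** — postures are corners of a normalized cube [−1, 1]³
   (axes: shoulder, elbow, wrist). An intermittent controller actuates
   only the joints that changed at each posture event, and each active
   axis follows the critically damped second-order law
   C(s)/R(s) = ω_n² / (s² + 2δω_n s + ω_n²), ω_n = 0.39, δ = 1,
   integrated by RK4. Trials steer a point sphere from the center into a
   target ball (radius 0.1) within 120 s and report time, trajectory
   length, posture changes, and final distance on failure.

Because no public recordings exist for this setup, the package includes a
synthetic 5-channel EMG generator whose envelopes carry exact
posture-specific synergy structure plus controllable noise; it backs the
entire test suite. See the methods vignette
(`vignettes/synergy-cube-methods.Rmd`) for the models, parameters and
design decisions.

## Worked example

```r
library(synergycube)

# a synthetic "subject": 8 postures, 3 true synergies, modest envelope noise
bank  <- make_synergy_bank(n_postures = 8, rank_true = 3,
                           noise_sigma = 0.15, seed = 1)
train <- training_envelopes(bank, hold_s = 10, seed = 2)   # 10 s per posture
test  <- evaluation_envelopes(bank, hold_s = 5, reps = 3, seed = 3)

clf <- train_round_robin(train, rank = 3, restarts = 30, seed = 1)
clf
#> posture_classifier: 8 postures, 28 pairwise synergy models (rank 3, 30 restarts)
#>   postures: FFS FFP FES FEP EFS EFP EES EEP

evaluate_classifier(clf, test, n_iter = 30)
#> Classification accuracy over 8 postures: 86.2%
#>  posture n_frames n_correct accuracy
#>      FFS       30        27    90.00
#>      FFP       30        28    93.33
#>      FES       30        30   100.00
#>      FEP       30        22    73.33
#>      EFS       30        27    90.00
#>      EFP       30        21    70.00
#>      EES       30        27    90.00
#>      EEP       30        25    83.33

# drive the sphere to a target with a scripted posture stream
cfg <- trial_config(target = default_targets()$t1)
run_trial(data.frame(time_s = 0, posture = "FFS"), cfg)
#> cube_trial: target reached in 3.56 s, 1 posture change(s), trajectory length 0.700

# how many posture commands does an awkward interior target need?
min_postures_to_reach(c(0.45, -0.7, 0))
#> reachability search (k_max = 4, grid = 25):
#>  target_id    x    y z min_k label
#>          1 0.45 -0.7 0     4     4
```

At the generator's default noise (`noise_sigma = 0.15`) the simulated
subject classifies around the 80–90% range — the regime reported for
human operators of the modeled system; at `noise_sigma = 0` the pipeline
is exact and accuracy is 100% for both the 5- and 8-posture
configurations. The trial row above reports the study's four performance
measures; `min_postures_to_reach()` certifies, by exhaustive grid search
over posture sequences and switch times, the smallest number of posture
commands whose trajectory enters the capture ball — here an awkward
target off every corner diagonal needs the full four commands.

A thin CLI over the same functions lives at `inst/cli/synergycube.R`
(subcommands `synth`, `train`, `evaluate`, `simulate`, `reachability`,
`experiment`).

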