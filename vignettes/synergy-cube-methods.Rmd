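---
title: "Single-muscle synergy control: models, parameters and design choices"
author: "synergycube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-muscle synergy control: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergycube)
```

## The problem

A single multifunctional muscle — the biceps brachii, which participates in
shoulder elevation, elbow flexion and forearm supination and is anatomically
compartmentalized — produces surface-EMG patterns that differ across static
upper-limb postures. `synergycube` implements a complete desk-scale model of
a myoelectric control scheme built on that observation: five EMG channels
recorded across the biceps are reduced to muscle-synergy activations, a
round-robin classifier maps activations to one of up to eight static
postures, and an intermittent controller converts the recognized posture
sequence into the movement of a point ("the red sphere") inside a normalized
cube, whose corners correspond to the eight postures. The package's users
are researchers studying synergy-based prosthesis control who need a
reproducible, fully scriptable version of this pipeline.

Postures are 3-letter codes over shoulder {F,E} x elbow {F,E} x wrist {P,S}
(flexion/extension, pronation/supination); the cube axes are the three
joints, normalized to [-1, 1].

## Pipeline stages

### 1. RMS envelopes

Raw EMG (2000 Hz by default) is reduced to sliding-window root-mean-square
envelopes: window 250 ms, hop 70 ms (500 and 140 samples), matching a 15 Hz
control link. Only complete windows produce frames — zero-padding at the
edges would bias the envelope statistics — and window/step widths are
converted to samples by `floor(ms * fs / 1000)` so framing is integer and
deterministic. A frame inherits the posture label of the span containing its
center sample; frames whose center falls in no labeled span stay unlabeled.
This single center-sample rule is deliberate: any windowed feature near a
posture transition mixes two postures, and the center rule resolves the
assignment unambiguously rather than pretending the ambiguity away.

### 2. Pairwise synergy extraction (NMF)

For each unordered pair of postures, the two envelope blocks are
concatenated frame-wise into a non-negative matrix V (channels x frames) and
factorized as V ~ W H with W, H >= 0 — W holding the synergy vectors, H the
per-frame activations. We use Lee–Seung multiplicative updates for the
squared Frobenius error, `max_iter = 500`, relative tolerance `1e-6`. The
multiplicative rules guarantee a monotone non-increasing objective, which
the test suite asserts at every iteration.

Initialization is random in W only (uniform, seeded); H is initialized from
the data as `t(W0) %*% V`, rescaled. Because column j of H then depends only
on column j of V, and the W update depends on V and H only through
permutation-invariant sums, the whole factorization is *exactly* equivariant
to frame reordering — permuting frames within a posture provably changes
nothing about the fitted model, a property the tests check to 1e-10.

NMF solutions are not unique, so each pair is factorized from `restarts = 30`
seeded initializations (`seed, seed + 1, ...`) and the restart whose
activation columns best separate the two postures is kept. Separation is
measured with Rousseeuw's silhouette index of the H columns labeled by
source posture, s(i) = (b(i) - a(i)) / max(a(i), b(i)), with s(i) = 0 for
singleton clusters and for points with a = b = 0. All pairwise fits draw
from the same restart-seed family: the pairs factorize different data, so
no diversity is lost, and training becomes exactly equivariant under
relabeling or reordering of postures.

The rank default is 3 per pairwise model (three synergies from five
channels). Whether the original system used rank 3 per pair or globally is
not determinable from the available material; per-pair rank 3 is the
package's reading and is exposed as a parameter. There is no automatic rank
selection by design.

A pairwise model whose selected silhouette falls below 0.05 (or whose two
cluster means coincide) is flagged *degenerate*: its two postures are
essentially indistinguishable and its votes are unreliable. The threshold is
the package's own; training warns but proceeds, and classification refuses
to run only when *every* model is degenerate.

### 3. Round-robin classification

An n-posture classifier is the ensemble of all n(n-1)/2 pairwise models
(28 for eight postures, 10 for five). At prediction time each model projects
the incoming envelope frame into its own activation space and votes for the
posture whose cluster-mean activation is nearer in Euclidean distance;
winner takes all. The projection solves non-negative least squares
min ||frame - W h||, h >= 0 — the source material trains on H-cluster means
but does not state the test-time mapping, and NNLS is the
minimal-assumption non-negative counterpart of the training factorization.
The active-set solver is used where W has full numerical column rank, with a
multiplicative-update fallback otherwise (rank-deficient W is routine when
the NMF rank exceeds the numerical rank of a clean envelope block).

Ties — either between the two distances inside one model or between vote
totals — are broken toward the posture earlier in the classifier's posture
ordering, and the result carries an `ambiguous` flag. Determinism was
preferred over randomized tie-breaking so that every classification is
exactly reproducible.

Evaluation mirrors the study cadence: per posture, 30 evenly spaced frames
of the evaluation envelope are classified (evenly spaced rather than random,
again for determinism) and accuracy is the percentage assigned to the true
posture.

An optional debounce (`predict(..., debounce = k)`) consumes a
classification only after k identical consecutive winners; the default is 1
(off), matching the modeled system, since misclassification-driven cursor
jumps are part of the phenomenon under study rather than a defect to hide.

### 4. The intermittent controller and sphere dynamics

Each recognized posture commands the corner of the cube it is assigned to
(default convention F -> +1, E -> -1 on shoulder/elbow; S -> +1, P -> -1 on
wrist; any of the eight consistent conventions can be selected, as the
original orientation is not fully specified). The controller is
*intermittent*: on a posture change only the joints that changed are
actuated. The special cases follow the modeled rule set literally:

* first posture of a trial: all three axes active;
* one or two joints changed: exactly those joints;
* all three changed at once: only the shoulder activates, and elbow/wrist
  stay inactive until a later change *not* involving the shoulder. While
  that lock holds, any change involving the shoulder re-applies the
  shoulder-only rule. Whether a pending reactivation should survive such an
  event is genuinely open; the literal reading was implemented and the lock
  state is exposed so variants can be built on top.

A deactivated axis holds its position exactly and its velocity is zeroed —
"remain inactive" is read as a hard hold, the source being silent on stored
momentum.

Each active axis follows the second-order law x'' = w_n^2 (r - x) -
2 d w_n x', with w_n = 0.39 (cube units) and d = 1 — critical damping, so a
step command approaches its corner monotonically with no overshoot.
Integration is classical RK4 with 10 sub-steps per 1/15 s control tick
(dt = 1/150 s); at that step the integrator matches the closed-form
critically damped response to well under 1e-6 over tens of seconds, and
trajectory lengths computed at dt and dt/2 agree to better than 0.1%.

Trials start the sphere at the cube center; a target (capture radius 0.1,
half the displayed diameter of 0.2) counts as reached the instant the point
sphere enters the ball — capture is evaluated at every integration sub-step,
with no dwell requirement ("touch" semantics). The four performance
measures are time to capture, trajectory length (cumulative Euclidean
distance along the numerical solution), number of posture changes, and the
final distance for failed trials at the 120 s limit.

### 5. Reachability: the minimum-command question

How many posture commands does it take to park the sphere anywhere in the
cube? One command can only drive the sphere along a straight diagonal
toward a corner; interior positions off those diagonals require *parking*
axes mid-range by deactivating them, and parking all three axes at three
independent values costs additional commands. The claim under test is that
four commands suffice anywhere and are sometimes necessary.

`min_postures_to_reach()` certifies minimal command counts by exhaustive
search: all posture sequences of length 1..k_max (consecutive postures
distinct, first command at t = 0), switch times on a uniform grid of 25
divisions of the 120 s trial, trajectories evaluated with the closed-form
critically damped segment solution sampled at 15 Hz. Levels are exhausted in
increasing k, so a capture at level k is a minimality proof with a witness
sequence; witnesses replay through the RK4 trial engine as an independent
check. Within a level the enumeration order is a deterministic shuffle —
exhaustiveness is unchanged, but capturing sequences are found early
instead of after a lexicographic desert of near-identical switch times.

The hardest interior positions combine one coordinate near zero with a
large companion coordinate: a freshly commanded axis has already traveled
~0.56 cube units by the first grid switch time, so pinning an axis near the
center requires a multi-leg reversal, while a companion near 0.7 sits
between the values reachable by early parking (~0.56) and late parking
(~0.89) and needs its own reversal — together they exhaust the command
budget. A systematic scan of the center-plane slab at the default grid locates the
four-command region there, with three commands sufficing outside it; since
a worst case is a property of specific positions, the package exposes the
deterministic probes that attain it (`worst_case_targets()`: one
coordinate zero, the others at 0.7). The reachability checks probe a
seeded sample of generic interior targets — verifying that four commands
always suffice — together with those probes, and find a maximum minimal
count of exactly 4 with certified witnesses.

## The synthetic-EMG generator

No public recordings exist for this setup, so the package generates its own
and states precisely what is and is not emulated. A `synergy_bank` draws a
shared non-negative basis W_true (5 x 3 by default, uniform on [0.2, 1]) and
per-posture activation vectors uniform on [0, 1]^3, redrawn until all
pairwise activation distances reach `separation = 0.35` — about the largest
separation reliably attainable by rejection for eight postures in the unit
cube of activations, and comfortably more structure than the noise scales
studied. The per-posture channel pattern is W_true h_true(posture), so the
generated envelopes carry exactly the low-rank structure the pipeline
assumes.

The time-domain signal is white Gaussian noise, amplitude-modulated so the
250 ms RMS envelope equals the channel pattern plus a Gaussian envelope
perturbation of scale `noise_sigma` (clipped at zero, redrawn every 250 ms).
The carrier is renormalized to exact unit RMS in 10 ms blocks; since the
500-sample window and the 140-sample hop are both multiples of the 20-sample
block, every interior frame reproduces the commanded envelope *exactly* at
`noise_sigma = 0`. That choice makes the noiseless case a sharp oracle: any
failure of the full pipeline to reach 100% accuracy there indicates an
implementation defect, not generator variance. No EMG spectral shaping,
motor-unit structure, or electrode-placement realism is attempted — the
pipeline consumes only RMS envelopes, so spectral realism would change
nothing downstream. Consequently, passing tests demonstrate correct
*mechanics* of the pipeline, not performance on real biceps recordings.

Protocol defaults mirror the modeled study: 10 s training holds per posture
and 3 x 5 s evaluation holds. The convenience wrappers generate each hold
as its own capture, so no envelope window straddles two postures; building
one continuous multi-span recording with `generate_emg()` instead yields
transition frames with mixed amplitudes, which is the realistic variant.

At `noise_sigma = 0.15` the simulated five-posture classifier lands near
80% accuracy — the regime of the modeled study's human subjects — and this
is the default of `run_experiment()`. The experiment driver couples the
greedy reaching policy's per-command error rate to each simulated subject's
measured misclassification rate, so noisier subjects both classify and
reach worse. The greedy "oracle subject" policy (lookahead one second,
command the posture whose activation-masked step most reduces distance to
target) is explicitly artifact plumbing to exercise trials end to end; it
models no human behavior, and the package deliberately does not reproduce
the human performance tables of the modeled study.

## Statistics

Condition comparisons use the classical paired t-test (per-seed five- vs
eight-posture accuracy) and the independent-samples t-test; the independent
test defaults to Welch (the source does not state pooled vs Welch; pooled is
available by flag). Degenerate inputs are resolved explicitly — identical
samples give t = 0, p = 1 — rather than erroring, because noiseless
simulations legitimately produce them. The 0.05 significance threshold is
reported, never hard-coded into logic.

## Numerical choices and limitations

* NMF epsilon guards (1e-12 in denominators) keep the multiplicative
  updates defined at zero entries; the monotonicity assertion allows
  1e-10 relative rounding slack.
* The reachability search is exact only at its grid: minimal counts are
  certified *at grid resolution 25 and 15 Hz sampling*. A finer grid could
  in principle lower a count by one where a trajectory grazes a capture
  ball between samples; at the studied radii the sphere moves well under
  0.02 units per sample, far below the 0.1 capture radius.
* Problem sizes in the test suite are the package's own desk scale: 2–3 s
  training holds for structural tests, full 10 s / 3 x 5 s protocol for the
  headline parameter-recovery checks, 20 seeds for the noise-monotonicity
  sweep with 5 restarts (the noiseless recovery checks use the full 30).
* Serialized classifiers store matrices at full double precision in JSON;
  round trips are lossless to IEEE double text conversion.
* The package models the digital pipeline only: analog amplification,
  rectification and filtering, firmware, GUI rendering, and human-subject
  behavior are out of scope.
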