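---
title: "Methods: head-body orientation integration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head-body orientation integration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hborient)
```

This vignette is the package's account of its methods: the generative model
behind the synthetic populations, the statistical procedures applied to
them, the decoding machinery, the parameters that matter, and the numerical
and design choices that were genuinely open.

## The scientific setting

Units in the ventral-bank superior temporal sulcus respond to heads and to
bodies, and their responses are modulated by each part's orientation about
the vertical axis. The question the analysis chain addresses is whether the
two orientations are encoded *jointly*: does a unit's head-orientation
tuning depend on the orientation of the body beneath it, and can a
population read out the signed head-body angle
`α = wrap(θ_head − θ_body) ∈ (−180°, 180°]` independently of the overall
orientation of the figure? The experimental designs encoded by
`make_stimulus_grid()` are:

* **E1** — 8 head × 8 body orientations (45° steps) per pose, in a
  monkey-centered (MC) and a head-centered (HC) presentation, plus isolated
  heads and headless bodies at the matched locations of the zero- and
  straight-angle configurations (76 conditions per pose and centering).
* **E2** — four angles (0°, ±90°, 180°) at four orientations plus 16
  standalone heads and 4 headless bodies (36 conditions, MC).
* **E3** — four angles at eight orientations, upright and inverted, plus
  isolated parts (88 conditions per pose, MC).

Isolated-part conditions are identified by their own orientation *and* an
`anchor_angle`, the head-body angle of the source configuration. In the
experiments the same part image can appear at several screen locations
(matched to different source avatars); the trial schema has no location
column, so the anchor serves as the location surrogate that keeps such
conditions distinct.

## The generative model

Each synthetic unit (`tuning_params()`) fires Poisson spike counts with
mean `rate × window` in three windows per trial (100-ms and 200-ms
baselines at the baseline rate, a 250-ms response window at the
condition rate). The condition rate is

```
rate = baseline + w_part · a_inv · gain · D
D_monkey = (1 − w_conj) · (f_H(θ_h) + f_B(θ_b)) / 2  +  w_conj · f_H(θ_h) · f_B(θ_b)
D_head = f_H(θ_h),  D_body = f_B(θ_b)
f_X(θ) = (1 − m) · v(θ; μ_X, κ_X) + m · (v(θ; μ_X, κ_X) + v(−θ; μ_X, κ_X)) / 2
v(θ; μ, κ) = exp(κ (cos(θ − μ) − 1))
```

with the von Mises bumps peak-normalized to 1 so that `gain` is in
spikes/s and the additive and conjunctive components are commensurable.
The parameters and their defaults:

| parameter | meaning | default |
|---|---|---|
| `baseline` | baseline rate (spikes/s) | 10 |
| `gain` | peak driven rate (spikes/s) | 20 |
| `kappa_head`, `kappa_body` | tuning concentration (0 = untuned) | sampled U(1, 3) |
| `mu_head`, `mu_body` | preferred orientations (deg) | sampled U(0, 360) |
| `w_conj` | conjunctive weight ∈ [0, 1] | 0 |
| `m_mirror` | mirror-symmetry weight ∈ [0, 1] | 0 |
| `c_tol` | centering tolerance ∈ [0, 1] | 1 |
| `a_inv` | inversion attenuation ∈ [0, 1] | 1 |
| `part_weights` | drive of monkey/head/body stimuli | 1 / 0.5 / 0.5 |

The defaults are the package's study conditions, chosen once: a ~10
spikes/s baseline with driven modulation up to ~2× baseline and moderately
broad orientation tuning is typical of temporal-cortex units; 8 trials per
stimulus and two subjects with balanced unit counts mirror the designs
above. The part weights make the additive case exact: with `w_conj = 0`
the expected whole-monkey net response equals the sum of the expected
isolated-part nets, so the monkey-sum index is 0 and sum- and
configuration-decoding carry identical expected signal.

Three structural choices deserve comment:

* **Centering tolerance** is modeled as a mixture: under the non-reference
  centering the tuned component is scaled by `c_tol` and a fixed,
  unit-specific pseudo-random pattern (a deterministic hash of the
  condition, drawn once per unit) enters with weight `1 − c_tol`. This
  reproduces graded MC↔HC tuning correlations without modeling retinotopy.
* **Inversion** multiplies the driven component by `a_inv`; the analysis
  chain only requires that inversion weakens responses and decodability,
  not a specific mechanism.
* **Units are statistically independent.** Inter-unit noise correlations
  are not modeled; the decoding stage assembles pseudo-populations from
  independently permuted trials, which makes independence consistent with
  the analysis itself. Consequences of real noise correlations for
  decoding accuracy are outside what the synthetic tests can show.

What passing tests on these populations do show: the statistical machinery
recovers the generative structure (additivity, conjunction, mirror
symmetry, centering tolerance, inversion attenuation) with calibrated
false-positive rates. What they do not show: behavior under non-Poisson
dispersion, latency dynamics, adaptation, or correlated noise.

## Screening and per-unit statistics

Screening follows a conjunctive three-stage rule (`screen_units()`): a
split-plot ANOVA on per-trial window rates (within factor: 200-ms baseline
window vs response window; between factor: stimulus; trials are the error
stratum) with an excitatory best-stimulus response; for the multi-unit
style experiments additionally a Kruskal–Wallis test across stimuli on raw
response rates and a maximum response z-score above 3, where the z-score
normalizes by the standard deviation of the per-stimulus mean baselines —
the literal form of its definition, deliberately not a pooled-trial SD.
"Excitatory" is operationalized as best-stimulus mean response above its
baseline; the best stimulus rather than a category mean is used because the
screening should not presuppose which conditions drive the unit.

The monkey-sum index is computed per orientation/pose/centering case in
which the whole monkey, its isolated head, or its isolated body evokes a
significant excitatory response (rank-sum test between baseline-window and
response-window trial rates, p < 0.05). The stated unpaired rank-sum test
is implemented even though the windows are paired within trials; a
signed-rank variant would be more powerful but is not what the procedure
specifies. The 100-ms baseline feeds these tests, matching the net-rate
convention (`net = response/0.25 s − baseline100/0.1 s`).

The head × body interaction ANOVA runs on `√(count + 3/8)`-transformed
per-trial response counts (raw counts behind `transform = FALSE`). One
calibration subtlety: units that are additive in *rate* are not exactly
additive after the square-root transform, so the interaction test carries a
small nonlinearity-induced inflation. At the default drive (gain ≈ 2×
baseline) the measured type-I rate on additive Poisson units is ≈ 0.05–0.06
at α = 0.05; much larger gain/baseline ratios would inflate it further.

## Decoding

`decode_angle_pair()` classifies two head-body angle classes after pooling
all orientations of each angle, so both classes contain identical multisets
of head orientations and of body orientations and only the conjunction can
separate them. The pipeline per resampling:

1. draw `n_units` units, balanced across subjects;
2. assemble a pseudo-population: for every stimulus, 8 population vectors,
   each unit's 8 trials permuted independently (`build_pseudopopulation()`);
3. eightfold cross-validation with orientation-balanced folds
   (`balanced_folds()`): each fold trains on 7 trials per orientation per
   class (56 with 8 orientations, 28 with 4) and tests on one;
4. a linear SVM with `C = 1` (`e1071::svm`, one-vs-one voting for
   multiclass). Features are standardized within each training set — a
   numerical-conditioning choice: the SMO solver is orders of magnitude
   slower on near-inseparable raw-rate problems, and standardization
   leaves every qualitative signature of the analysis unchanged;
5. mean test accuracy across folds, averaged over resamplings.

The **balance guard** is the anti-artifact core: `balanced_folds()` errors
on any class construction whose head- or body-orientation multisets differ.
The package also exposes `balanced = FALSE`, a deliberate demonstration of
the artifact the guard prevents: each fold then holds out one whole
orientation per class, staggered between the classes, so the training sets
over-represent different orientations. On a purely orientation-tuned
additive population this drives accuracies far *below* chance (orientation
features learned for the wrong class), which is exactly why naive fold
construction is dangerous in pooled-orientation designs. The balanced-fold
accuracies center on chance with a tighter spread than the permutation-null
runs; their extreme tails can still brush the null's 2.5th percentile in
long runs, so the demonstration is sharp for the unbalanced side and
tail-sensitive for the balanced side.

**Permutation nulls**: class labels of the pooled trials are permuted once
per run, the identical pipeline is re-run (units re-drawn per run, folds
random within permuted classes since orientation balance is undefined after
permutation), and the min–max band over 200 run means is reported. Each
run averages `null_resamples` resamplings (default 1 at desk scale; the
reference procedure used the same count as the main decoding — increasing
it narrows the band monotonically).

**Comparisons** between decodings (`compare_decodings()`) use paired
resamplings (same master seed, hence the same unit draw per resampling);
the p-value is the percentile of zero in the difference distribution,
two-tailed at 0.025.

**Sum decoding** (`decode_from_sums()`) replaces each configuration's
response with the trial-wise sum of the matched isolated head and body
*net* responses (net, to avoid double-counting baseline). Two details
matter. First, trial permutation happens at the level of the unique
isolated-part stimuli: a headless body shared by several configurations
keeps a single permutation. Second, folds equal assembly slots and are
shared across classes. Both rules exist for the same reason: a shared part
trial must never sit in the training set of one class while it is being
tested in the other, which would bias accuracy below chance.

**Orientation decoding** (`decode_orientation()`) is an 8-way
classification of the zero-angle configurations, run separately upright and
inverted; `decode_inversion_effect()` pairs the unit draws and summarizes
the upright-minus-inverted difference over means of 10 resamplings.

**Neuron dropping** (`neuron_dropping()`) ranks units by the drop in mean
accuracy when each is removed (leave-one-out deltas on paired resamplings)
and reports a top-k accuracy curve plus the fraction of the 10 best units
with significant head × body interaction and with a significant one-way
angle effect. The reference analysis names no procedure; leave-one-out
deltas are this package's documented stand-in.

## Mirror symmetry

`marginal_tuning()` normalizes a unit's 64 mean responses by its maximum
and then averages the 8 conditions sharing each head (or body) orientation;
normalize-then-average is fixed because the operations do not commute.
`mirror_distance_matrix()` computes `1 − Pearson r` between the population
vectors of every orientation pair (distances across the unit dimension,
standard representational-distance practice; whether the reference analysis
averaged per-unit distances instead is not determinable from its
description, and the population form satisfies the stated metric). Note
that trial noise attenuates across-unit correlations, so even a perfectly
mirror-symmetric population shows a small positive distance between ±90°;
the signature is the *contrast* with non-mirror pairs.

## Numerical choices and degenerate inputs

* Orientations live on {0°, 45°, …, 315°}; signed angles are derived, never
  stored; 180° (not −180°) represents the straight angle.
* Zero-variance cases are dropped or failed explicitly: degenerate
  split-plot fits fail the screen, zero MSI denominators drop the case,
  zero-variance correlation vectors return `NA`, reliability splits with
  constant halves are skipped, nonpositive reliabilities invalidate
  normalization (and normalized correlations above 1 are deliberately not
  clipped).
* A degenerate SVM training set (identical classes) yields a deterministic
  first-class prediction; accuracy then sits at chance by the symmetry of
  fold construction.
* Sub-seeds are derived deterministically from one master seed, below
  2^31, so unit draws pair across compared decodings and every run is
  bit-reproducible.

## Problem sizes

The bundled tests and the acceptance script run the full chain at reduced
but statistically meaningful sizes, the package's own choice of desk-scale
conditions: 60-unit populations (30 per subject), 8 trials per stimulus,
3–20 resamplings per decoding (100 for the inversion contrast), 200
permutation runs per null band with one resampling each, 100–200 simulated
units or cases for calibration rates, and 500 units for the
interaction-ANOVA calibration. All sizes are parameters, and the
full-scale settings (100–1000 resamplings, nulls averaging 100 resamplings
per run) are reachable through the same interfaces.

## Known limitations

* Poisson noise only; no overdispersion or noise correlations.
* No latency or temporal dynamics — only window counts.
* The centering-tolerance mixture is a phenomenological stand-in for
  retinotopic position effects.
* The neuron-dropping ranking is a stand-in for an unspecified procedure.
* Real-data quantitative values (median correlations, absolute decoding
  accuracies of recorded populations) are outside the scope of synthetic
  validation; the tests check structural recovery and calibration, not
  those numbers.
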