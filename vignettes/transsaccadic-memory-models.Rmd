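---
title: "Generative models of transsaccadic spatial working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative models of transsaccadic spatial working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locuswm)
```

## The scientific problem

Every saccade displaces the retinal image, yet remembered locations feel
stable. One influential account holds that locations are stored in
eye-centred (retinotopic) coordinates and *remapped* across each saccade
using an internal copy of the eye-movement vector. `locuswm` implements a
family of generative models that make this account — and its competitors —
quantitative for a continuous-report task in which two coloured squares
must be remembered across 0, 1 or 2 instructed saccades, and the probed
item's location is reproduced on screen.

The package's job is inference: given per-trial location responses, which
representational scheme best explains the pattern of errors across the four
saccade conditions, and what are the credible values of its parameters?

## The task generator

`generate_session()` builds synthetic sessions that respect the task's
design constraints: a 3 × 5 grid of candidate frame centres (spacing 10.1°,
i.e. the 9.8° frame plus a 0.3° gap), items placed uniformly inside the
frame at least 3.82° from the fixation cross, instructed saccades of at
least 8.5° (automatic on this grid, where distinct centres are ≥ 10.1°
apart), four equiprobable conditions, per-trial colour-wheel rotation, and
a strictly increasing event timeline. Each trial consumes its own derived
seed, so any single trial can be regenerated in isolation.

Timing defaults are: 1 s item presentations separated by a 0.5 s interval,
the wheel 0.5 s after item 2, the colour response 2 s and the location
response 3 s after wheel onset, and saccades executed 0.2 s after the frame
change or wheel onset. Real sessions have variable response latencies; the
generator's are deliberately fixed, which concentrates the retention
variables on a small set of values (τ ∈ {3.5, 5} s at the defaults). The
timing variables per item follow from the condition: the number of
saccades since an item was viewed is (0, 0), (1, 0), (1, 1) and (2, 1) for
items 1 and 2 in the no-saccade, saccade-after-1, saccade-after-2 and
two-saccade conditions respectively — in the saccade-after-2 condition both
items share one fixation, so the wheel saccade counts for both.

## The seven models

All models share the idea that memory degrades by diffusion: response
variance grows linearly in elapsed time. They differ in *what* diffuses.

| # | Model | Parameters |
|---|-------|------------|
| 1 | Allocentric | `alloc_decay`, `alloc_enc` |
| 2 | Dual (retinotopic) | `radial_enc`, `radial_decay`, `angular_enc`, `angular_decay` |
| 3 | Dual + fixation decay | … + `fixation_decay` |
| 4 | Dual + saccade update | … + `saccade_enc`, `saccade_decay` |
| 5 | Dual + interference | model 2 + `interference` |
| 6 | Fixation decay + interference | model 3 + `interference` |
| 7 | Saccade update + interference | model 4 + `interference` |

Model 1 places independent normals on the response's Euclidean coordinates
about the stimulus with variance `alloc_enc + alloc_decay·τ`. Models 2–7
first normalise each trial (`normalize_trials()`): the origin moves to the
fixation at which the probed item was viewed and the plane rotates so the
target lies at angle 0; the same rigid transform is applied to the response
and the distractor. The likelihood is then a normal on the radial
coordinate times a normal on the angular residual, with the variance
schedules shown in the README. Fixation decay begins at the first saccade
*after* the item (time `t`), capturing loss of the remembered origin;
saccade updating charges a per-saccade encoding cost (`n·saccade_enc`) plus
decay of each stored saccade vector (`saccade_decay·(t+T)`). Interference
mixes in the distractor's density — evaluated at the distractor's own
coordinates and timing variables — with weight `w`.

Design choices a reader should know (each is a deliberate reading of an
under-specified point):

- The second argument of every normal is a **variance**, so decay is
  diffusion-consistent (variance linear in time), not an SD schedule.
- Fixation and saccade terms are added to **both** the radial and angular
  variances; the two components share those parameters.
- The angular residual is wrapped into (−π, π] before evaluating the
  (unwrapped) normal density, preventing spurious 2π discontinuities.
- The radial normal is **not** truncated at r = 0; consequences are
  discussed under *Identifiability* below.
- Scale parameters are `exp`-transformed, the interference weight is a
  sigmoid; inference lives entirely in the unconstrained space.

## Inversion

`locus_fit()` maximises the log-joint (dataset log-likelihood plus the
`N(0, 1/8·I)` log-prior) with a damped Newton scheme: central
finite-difference gradient and Hessian (step 10⁻³ in unconstrained space —
large enough that second differences of log-joints in the hundreds of nats
keep ~9 significant digits, and exact for the quadratic test cases),
Levenberg–Marquardt damping that multiplies tenfold whenever a proposed
step fails to improve the log-joint, initialisation at the prior mean (so
fits are deterministic), convergence when the free energy improves by less
than 10⁻⁴ nats, and at most 128 iterations. The posterior covariance is the
inverse negative Hessian at the mode, diagonally jittered to positive
definiteness if needed, and the evidence approximation is

```
F = log-joint(mode) + (d/2)·log 2π + (1/2)·log det Σ.
```

With no data this is exactly 0 (the prior terms cancel), and in the
linear-Gaussian case it equals the analytic marginal likelihood — both are
enforced by tests. A parameter the likelihood ignores leaves F unchanged
under this prior, so irrelevant parameters are evidence-neutral rather than
penalised; parsimony pressure comes from the prior cost of moving
parameters away from zero.

## Model selection and recovery

`compare_models()` sums free energies over subjects per model and applies a
softmax; the Bayes factor is reported as the ratio of the top two posterior
probabilities. This is fixed-effects accumulation — every subject is
assumed to share one generative process; random-effects selection is out of
scope.

`recovery_analysis()` simulates subjects from each generating model with
parameters drawn from the prior, fits every candidate model to every
dataset, and softmax-normalises the accumulated evidence per generating
model into a column-stochastic confusion matrix. For a designated model it
also correlates generating and recovered (posterior-mode) parameters. Two
behaviours are worth expecting rather than being surprised by: no single
model dominates every column, and the most complex model is often *not* the
best explanation of its own prior-sampled data — nested models win whenever
the sampled saccade or interference effects are too small to pay for their
extra parameters. The interference weight is the best-recovered parameter;
the decay parameters recover weakly at prior scale (see below).

## Group inference

`fit_peb()` is a second-level linear model over subjects' posterior modes,
run marginally per parameter: `θᵢ ~ N((Xβ)ᵢ, σ²_between + vᵢ)` with `vᵢ`
the subject's first-level posterior variance, so uncertain subjects weigh
less. `σ²_between` is estimated by REML inside the precision-weighted
model. The default prior on β is flat, making the posterior coincide with
generalised least squares (a proper Gaussian prior is available via
`prior_var`); `contrast_probability()` turns the Gaussian posterior into
`P(β_A − β_B > 0)`, flagged at 0.95.

`score_regression()` regresses a per-subject score on posterior-mode
parameters: scores beyond 2 SD of the mean are excluded, the rest are
mean-centred, regressors are centred and divided by their SD (making the
fit invariant to affine rescaling of any regressor), and the linear model —
including a log noise variance — is inverted with the same Laplace
machinery under `N(0, 1/8)` coefficient priors. The log noise variance gets
a broad prior (variance 16): noise level is a measurement property the data
should set, and a tight prior would stop a near-exact linear relationship
from reaching the variance-explained ceiling. Variance explained is
`100·(1 − var(residuals)/var(scores))` at the posterior-mean predictions.

## Gaze processing and compliance

Traces are 1000 Hz (time in ms, positions in degrees, pupil in arbitrary
units). `remove_blinks()` masks zero-pupil samples plus samples within
±50 ms whose pupil rate-of-change exceeds the 99.5th percentile of the
*background* (away-from-blink) rate — thresholding on the whole-trace rate
would let the blink ramps inflate their own criterion. Fixations are
maximal runs within 2.5° of a target lasting ≥ 150 ms, in 1 s epochs after
each stimulus onset. Saccades require instantaneous speed above 150°/s for
more than 10 ms *and* net displacement above 9.2° (the perifoveal radius);
net displacement, not path length, is used. Velocity is estimated by
central differences over a ±5 ms stencil after 5-sample median smoothing:
with realistic measurement jitter a single-sample central difference
fragments the supra-threshold run and a genuine saccade would be missed,
while the wider stencil still saturates on any 8.5°+ instructed saccade.

The per-condition rule table generalises the one worked example the task
description gives: fixations on both items always; the no-saccade condition
forbids any large saccade in any epoch; the one-saccade conditions require
their saccade in the right window (between the items, or after wheel
onset) and the saccade-after-1 condition forbids one after wheel onset; the
two-saccade condition requires both. A trial whose required epochs are
fully masked is *indeterminate*, which is reported distinctly from
non-compliant.

`simulate_gaze()` closes the loop for testing: piecewise-constant fixations
with 40 ms linear saccade ramps, plus optional jitter built from smoothed
white noise rescaled to the requested SD. The smoothing is intentional:
white noise of 0.5° SD at 1000 Hz would imply ~500°/s sample-to-sample
velocities, which no fixating eye produces and which would make any
velocity-based detector meaningless. Synthetic non-compliance injects a
condition-appropriate violation (an in-epoch excursion, a forbidden
post-wheel saccade, or omission of a required saccade).

`behavioural_errors()` computes condition × item mean location errors
(Euclidean, degrees) and colour errors (shortest wheel arc, [0, π]) over
compliant trials, and the saccade cost: the two-saccade condition's mean
location error minus that of the matched saccade-after-the-other-item
condition, isolating the cost of a saccade made immediately after the
probed item.

## Identifiability, and what the synthetic tests do and do not show

Two structural features limit parameter recovery at prior scale
(`κ ~ N(0, 1/8)`, natural scales near 1):

1. **Angular wrapping saturates.** An angular variance of 1 rad² or more is
   barely distinguishable from a uniform angle, whose wrapped variance caps
   at π²/3. Prior-scale draws routinely imply Σ_θ of several rad², so
   angular (and, through the shared terms, saccade/fixation) decay
   parameters recover weakly — visible in the recovery analysis as modest
   correlations for decay parameters alongside strong recovery of the
   interference weight.
2. **The radial density folds at r = 0.** The likelihood sees only the
   non-negative radius computed from the response coordinates, while the
   untruncated radial normal puts mass below zero when Σ_r is large
   relative to the target eccentricity (≥ 3.82°). A folded draw lands with
   its angle flipped by π, contaminating the angular estimates.

Both effects belong to the model, not to the optimiser — the conjugate and
no-data oracles pin the inversion itself to analytic answers.
Calibration-style tests (posterior coverage; recovery of known parameters
within 3 posterior SD at 2000 trials) therefore use generating values
chosen once from an identifiability analysis: total angular variance below
~1 rad² at the longest retention and radial fold mass below ~0.2%, with
unconstrained values otherwise as close to the prior mean as those
constraints allow. Passing them shows the inversion is consistent and
approximately calibrated where the model is well-posed; it does not certify
recovery at arbitrary parameter values, and none of the synthetic checks
speak to features real data would add (variable response latencies,
response biases, non-Gaussian error tails, lapses).

## Problem sizes and runtimes

The test-suite settings are the package's reference conditions: sessions of
160 trials (40 per condition); recovery with 16 subjects per generating
model over the full 7 × 7 model space; interference-recovery medians over
five or more seeds; 2000-trial single-subject fits for the known-parameter
checks; two 20-subject groups for the PEB dissociation (offsets of +0.75 on
the radial-decay and interference parameters, between-subject SD 0.25);
40-trial jittered compliance batches. A single 160-trial, 7-parameter fit
takes a few hundred milliseconds on one core.

## Known limitations

- Colour responses are carried through the IO but never modelled.
- Fixed-effects model selection only; no random-effects or protected
  exceedance probabilities.
- PEB is marginal per parameter; a joint-parameter second level is not
  implemented.
- The generator's latencies and saccade times are fixed constants, so the
  synthetic timing variables take few distinct values; real datasets spread
  them continuously.
- Angular likelihoods are unwrapped normals evaluated at wrapped residuals,
  not von Mises densities, matching the modelling choice they implement.
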