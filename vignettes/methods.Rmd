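---
title: "Subset reduction and estimation for strain-based cardiac model personalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subset reduction and estimation for strain-based cardiac model personalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainreduce)
```

## The problem

Mechanistic models of ventricular mechanics can, in principle, translate a
patient's regional strain curves into regional tissue properties --
contractility, passive stiffness, activation delay -- that are not directly
measurable. In practice such models carry on the order of a hundred
parameters, interact nonlinearly, and are fitted against a handful of noisy
echo-derived strain traces. Most parameters are either unimportant for the
strain output or not identifiable from it, and estimating all of them at
once produces meaningless numbers. `strainreduce` implements a two-stage,
model-agnostic pipeline that first discards parameters the output is
insensitive to, then iteratively removes parameters the *data* cannot pin
down, validating every removal by whether the cohort can still be fitted
about as well.

The pipeline operates on dimensionless inputs: every parameter's physical
domain is mapped linearly onto `[0, 1]`, so the machinery never needs to
know what a parameter means. A forward model is any function from a point
of the unit hypercube to per-segment strain traces; the bundled toy
simulator (below) is one such function, and a user's model adapter is
another.

## Stage 1: Morris screening

Sensitivity screening uses Morris elementary effects on a `z = 8` level
grid with step `Delta = z / (2 (z - 1)) = 4/7`. A trajectory perturbs each
parameter exactly once, in random order, from a random grid point; the
elementary effect of a parameter on an output is the signed difference
quotient along that step. The screening statistic `mu*` is the mean
absolute elementary effect over trajectories, computed per output. The
outputs are 35 morphology indices: for each of the five wall segments,
times to 10/50/90% of total shortening, pre-stretch, systolic strain,
post-systolic strain, and peak strain.

A parameter is dropped only when its `mu*` lies strictly below the
parameter-average for *every* output (ties retain), so a parameter that
matters anywhere survives. Screening repeats on the survivors until a
round removes nothing; a leave-one-out check over trajectories flags
rankings that hinge on a single trajectory. Trajectories containing a
crashed (non-physiological) simulation are discarded whole and counted, so
reported budgets refer to successful trajectories.

## Stage 2: identifiability-driven reduction

The second stage brings in measured data. A Sobol low-discrepancy sweep
(unscrambled, Joe-Kuo direction numbers, zero point skipped) samples the
active subset once; every sample is simulated once and scored against each
subject. Cycle time is part of the input space, which is what lets one
sweep serve all subjects. For each subject the best `N_b = 100` samples
are kept and, per parameter, summarized by the first-harmonic diaphony

\[ d_i = \Bigl| \tfrac{1}{N_b} \sum_b e^{2\pi i x_{b,i}} \Bigr|, \]

the modulus of the mean unit phasor of the best-set coordinates: `d = 0`
for a homogeneously spread coordinate (the data do not care where the
parameter sits) and `d = 1` when the best fits agree on one value. The
worst case over subjects ranks the parameters; those below a configurable
quantile (default 0.25) of the ranking are proposed for omission, fixed at
their normalized reference values.

Every proposal is validated by re-fitting: constriction particle swarm
optimization (population 30, `w = 0.729`, `c1 = c2 = 1.49445`) per subject
on the old and the new subset, seeded from each subject's best sweep
samples with zero initial velocity. The proposal is accepted when the mean
cohort error of the reduced subset stays within `(1 + tol)` times the
previous mean (default `tol = 0.5`, mirroring the roughly 50% error steps
that separate successively reduced subsets in published applications of
this strategy), plus an absolute slack of 0.01 -- an `E_SS` difference
corresponding to an RMS strain deviation of roughly 0.15% over a
half-second window, far below echo noise, so that comparisons between two
essentially perfect fits are not decided by numerical noise. A rejected
proposal is retried with half as many omissions before the loop stops.

Three implementation details matter for correctness and are easy to get
wrong:

* **Projected seeds must be re-scored.** When the best points of a larger
  subset seed the swarm of a smaller one, their cached errors belong to
  the larger subset; each seed is re-evaluated under the reduced
  objective before use.
* **Seed diversity.** Projection can collapse the seeds onto near-identical
  points; identical zero-velocity particles have no dynamics. Duplicate
  seeds are collapsed and, if the whole seed cloud sits inside the
  energy-convergence ball, the worst half is re-seeded with Sobol points
  so the stopping rule measures actual contraction.
* **Deterministic validation.** The swarm seed is derived from the subset
  content, so validating a subset against itself reproduces the identical
  fit (ratio exactly 1), and reruns with the same root seed are bit-exact.

After the loop stops, a **final estimation stage** re-sweeps the accepted
subset with fresh Sobol points and runs one full swarm fit per subject.
The validation fits use the standard energy tolerance (0.1, below which
all particles' squared velocity plus squared distances to their personal
and the global best must fall); the final stage tightens it to 0.01.
Validation only compares two fits obtained under the same rule, so the
loose tolerance is harmless there, but reported estimates should be
limited by identifiability rather than by the stopping rule.

## The fit error

The objective is the window-integrated squared strain difference summed
over the five segments plus a cycle-time penalty:

\[ E_{SS} = \alpha \sum_{seg} \int_{t_{QRS}}^{t_{50,relax}}
   (\varepsilon_{model} - \varepsilon_{meas})^2 \, dt
   + \beta (T_{model} - T_{meas})^2, \]

with `alpha = 1 s^-1`, `beta = 0.1 s^-2`. The window runs from QRS onset
to 50% relaxation of the global RV strain (the mean of the three RV
free-wall segments), measured toward the end-of-cycle value rather than
toward zero so that baseline drift in the measurement does not corrupt
the endpoint. Integration uses the trapezoid rule on a common 2 ms
resampling; series are extended with their boundary values beyond their
support, since a cycle-time mismatch is penalized by the `beta` term
rather than by an artificial area contribution. Crashed simulations get
infinite error everywhere (sweep, swarm, and screening discards).

For the morphology indices, "total shortening" is measured from the
pre-peak maximum (the pre-stretch level), not from zero: the time-to-X%
crossings are then well defined for curves that lengthen before they
shorten, which is precisely the pathological morphology of interest.
Flat curves yield a degenerate-index flag with zero crossing times
instead of an error, so screening never crashes on a dead segment.

## The bundled forward model

The toy simulator is a phenomenological stand-in, not a reimplementation
of any published cardiovascular model: the pipeline is model-agnostic, so
its test model only needs the right strain phenomenology, speed, and a
crash mode. Per time sample the three RV free-wall segments share a
common tension `F(t)`; each segment obeys `F = k_s u_s + c_s a_s(t)` with
`u_s` its strain, `k_s` an effective stiffness and `c_s` an effective
contractility. `F(t)` is the unique tension making the mean RV strain
follow a prescribed global shortening waveform `G(t)`, after which each
segment's strain is explicit; the septum and LV free wall are single
segments loaded by the same tension. All strain is percent, negative
means shortening, and traces are referenced to zero at QRS onset.

Two shape choices carry the phenomenology:

* `G(t)` rises slowly (quartic) from AV-delay to peak shortening at
  pulmonary valve closure, then relaxes over half the remaining diastole.
  A cycle therefore has a realistic end-systolic peak and a diastolic
  tail, the fit window ends after valve closure, and a healthy segment
  shows zero post-systolic strain.
* `a_s(t)` is a twitch: a fast rise over the first 60% of the segment's
  systole, a plateau to end-systole, then smooth decay. Its early-rise
  shape is deliberately different from the slow drive, for two reasons.
  Phenomenologically, early active-tension imbalance between segments
  surfaces as pre-stretch of the weak or late segment before global
  shortening takes hold. Statistically, a segment's strain is a mixture
  of `F(t)/k_s` and `c_s a_s(t)/k_s`; if the two temporal shapes were
  proportional, stiffness and contractility would only be identifiable
  through their ratio. With distinct shapes both become estimable, which
  is what makes stiffness recovery a meaningful end-to-end target.

Effective parameters couple the registry to the mechanics: contractility
`SfAct` scaled by wall reference area and (length-dependent activation)
zero-stress sarcomere length; stiffness `kLin` scaled by the
passive-stiffness exponent `k1`, wall volume and mean arterial pressure;
activation delay `dT` shifting the twitch; contraction/relaxation time
constants stretching its duration; shortening velocity warping its rise.
A constant pre-stretch offset was deliberately *not* used for the
sarcomere length: constant offsets cancel exactly under QRS re-referencing
and would have made the parameter a silent no-op. The placeholder
parameters (`res1`/`res2` per segment, `glob01`..`glob44`) are never read
-- they exist so screening and reduction have genuinely irrelevant inputs
to find.

The crash predicate marks a point crashed when any wall segment combines
a normalized stiffness coordinate below 0.06 with a normalized
contractility coordinate above 0.90 -- a weak-wall/over-driven corner
occupying about 3% of the unit hypercube, so Sobol sweeps succeed at
roughly the 96-98% rates typical of such models, while the coarse Morris
grid (which concentrates mass on the bounds) loses a noticeable fraction
of trajectories, exercising the discard logic.

The model grid is 2 ms. A single evaluation costs well under a
millisecond, which is what makes hundreds of thousands of evaluations per
test run feasible.

## The synthetic cohort

Virtual subjects consist of a ground-truth point and an echo-like
measurement. Three archetypes mirror the clinical staging of
arrhythmogenic cardiomyopathy screening: `concealed` (near-reference),
`electrical` (markedly delayed basal activation, moderately delayed mid),
and `structural` (reduced mid/basal contractility, increased mid/basal
stiffness, delayed base). On top of the archetype, *every* subject draws
regional heterogeneity (s.d. 0.12 on the normalized scale) in the six
disease-prone mid/basal tissue parameters, plus individual cycle time and
AV delay: recovery of a parameter is only a meaningful target when its
ground truth varies across subjects by more than the estimation noise.
Cardiac output and relative systole duration stay at reference across
subjects: in this toy model they are fully compensable by tissue
rescaling and timing shifts respectively, so subject-level variation in
them would make the remaining estimates identifiable only up to an
equivalence class. Truth draws falling in the crash region are rejected
and redrawn.

The measurement model resamples the simulated strain to 60 Hz, adds
i.i.d. Gaussian noise (s.d. 0.5% strain) and a linear drift drawn
uniformly in +/-1% per cycle, then re-zeroes at QRS onset. Drift is on by
default precisely so the 50%-relaxation window rule earns its keep. What
the generator does *not* emulate: speckle-tracking image formation,
frame-to-frame tracking artefacts, inter-observer variability, or
beat-to-beat variation. Passing the end-to-end tests therefore shows the
pipeline recovers what this noise model allows -- it does not certify
performance on clinical data.

## Problem sizes and numerical choices

Desk-scale defaults keep a full pipeline run in minutes on one CPU:
Sobol sweeps of `2^14` points per round (the method scales to millions of
samples by configuration, nothing in the code changes), best-set size
100, screening budgets of tens of successful trajectories, validation
swarms capped at a few hundred iterations. The end-to-end tests use a
10-subject cohort (4 concealed / 3 electrical / 3 structural); the
generator's default is 15 subjects at the 6/4/5 stage mix.

Other numerical choices: Sobol dimensions up to 128 are supported by the
bundled direction-number table; `z` must be even so Morris steps stay on
the grid; strict inequality in the screening criterion retains tied
parameters; diaphony ranking ties break by registry order; the registry
orders group-major (RV apex, mid, base, septum, LV free wall, global) and
alphabetically within group so every run enumerates identically. All
randomness flows from one root seed through named stage seeds
(`stageSeed`), so any stage can be reproduced in isolation.

## Known limitations

The toy model has deliberate structural redundancies (cardiac output,
relative systole duration) and its stiffness identifiability, while
real, is the weakest of the disease parameters -- rank correlations for
stiffness sit visibly below those for contractility and delay. The
reduction loop's acceptance rule is a ratio test against the previous
subset, so a long chain of individually acceptable steps can drift; the
audit trail records every round so such drift is visible. The energy
stopping rule measures swarm contraction, not optimality; multimodal
objectives can trap it, which is why estimation is seeded from the sweep
rather than from random points.
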