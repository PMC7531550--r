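---
title: "Models and methods: representational analysis of multistep task episodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: representational analysis of multistep task episodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episodeRSA)
```

## The paradigm and the question

`episodeRSA` implements an analysis pipeline for event-related fMRI
experiments in which participants execute memorized multistep task
episodes. The paradigm has a strict hierarchy: two *rooms* (kitchen,
bathroom), three everyday *tasks* per room, four ordered *steps* per
task, and a unique *item* (image) attached to every task-step. On each
45 s episode a cue names the task; the participant then identifies the
current step's target item in three consecutive four-item visual-search
arrays per step (9 s per step). Distractor images are drawn from a
single *distractor task* in the other room, so every array contains two
images from each room.

The scientific question is how cortical systems represent the different
levels of this hierarchy — room, task identity, step position, and item
— and the package's core statistic is a linear decomposition of
cross-validated pattern dissimilarities into exactly those components.

## Run design

Each run holds 36 episodes plus an initial dummy episode, ordered so
that **every ordered pair of tasks (including repeats) occurs exactly
once** among consecutive episodes. This is an Eulerian path on the
complete digraph with self-loops over the six tasks; `transition_balanced_order()`
constructs it with Hierholzer's algorithm using seeded random edge
choices, so all balanced orders are reachable and reproducible.

Timing within the run is rigid in one respect and jittered in another:
first-step onsets sit on an exact 45 s grid, while the fixation between
cue and first step is drawn from Uniform(1.5, 7.5) s. Because the
interval from the last step of one episode to the first step of the
next is fixed at 9 s (fixation + 1 s cue + fixation), the post-episode
fixation of episode *k* is forced to `8 - f_pre(k+1)`. This coupling is
the unique scheme satisfying the 45 s grid, the jitter range, and the
9 s gap simultaneously.

Distractor tasks are balanced so each cued-task x distractor-task
combination occurs exactly twice per run (36 episodes / 18
combinations). Pure random assignment would leave some combinations
unobserved in a finite run and their condition patterns inestimable;
balancing guarantees every one of the 72 conditions has two episodes.

`select_efficient_order()` simulates 1000 candidate orders (the default)
and keeps the one maximizing mean estimation efficiency
`e(c) = 1 / (c' (X'X)^-1 c)` over the 15 pairwise task contrasts, with
`X` the HRF-convolved per-task episode regressors plus a block mean.
Ties break to the lowest candidate index. Efficiency scoring uses a
0.5 s time grid — episode boxcars are 36 s long, so finer sampling
changes scores negligibly while dominating runtime.

## GLMs

Two models are fitted per run, both by per-voxel OLS
(`fit_ols()`), both high-pass filtered at 1/128 Hz:

* **FIR model** (`build_fir_design()`): a 90 s window starting at the
  first-step onset of every even-numbered episode is covered by sixty
  1.5 s boxcar regressors, separately per cued task of the anchoring
  episode. Windows tile the run exactly because episodes are 45 s;
  the final window is truncated at the run end (with a warning), not
  dropped. The dummy episode and episode 1 are covered by a separate
  non-interest bin set, and windows containing an error episode use
  their own shared set.
* **Event model** (`build_event_design()`): per cued x distractor
  combination, each step gets a 0 s *onset* regressor and a 9 s *epoch*
  regressor, plus one 0 s *offset* regressor at episode end — 162
  regressors of interest. The cue gets separate onset and epoch
  (cue-to-first-step) regressors; error episodes (strictly more than
  25% errors among their 12 responses, `flag_error_episodes()`) are
  relocated to a separate per-step nuisance set; error searches are 2 s
  nuisance events. All task regressors are convolved with a canonical
  double-gamma HRF (peaks at 6 s and 16 s, response/undershoot ratio 6,
  32 s support) on a microtime grid of 16 bins per TR, with 0 s events
  as unit impulses at the nearest microtime bin.

The error-episode set is deliberately *per-step* (four onset/epoch pairs
plus an offset): a single shared onset/epoch pair cannot fit
step-specific activity, and the misfit would contaminate the residuals
that later calibrate the noise model.

High-pass filtering (`highpass_filter()`) residualizes against
`K = floor(2T / cutoff) + 1` non-constant discrete-cosine functions and
is applied identically to data and design; the block-mean column is left
alone. It is an orthogonal projection, hence idempotent, and the
residual degrees of freedom passed downstream subtract both the design
rank and `K`.

The 72 condition patterns entering RSA are the average of each
condition's onset and epoch betas (`average_condition_patterns()`).

## Cross-validated LDC and the RDM

Pattern dissimilarity is the linear discriminant contrast
(`crossvalidated_ldc()`): the pattern difference of one run projected
onto the Fisher discriminant fitted on the other run, averaged over both
directions,

$$d_{AB} = \tfrac12\left[(u_{A1}-u_{B1})^\top \hat\Sigma_2^{-1}
 (u_{A2}-u_{B2}) + (u_{A2}-u_{B2})^\top \hat\Sigma_1^{-1}
 (u_{A1}-u_{B1})\right],$$

a cross-validated estimate of squared Mahalanobis distance. Because the
two runs carry independent noise, `d` is unbiased around zero when the
true distance is zero; the sign is preserved (no truncation), which is
essential for testing coefficients against zero at the group level.

The per-run noise covariance (`estimate_noise_covariance()`) is the GLM
residual covariance shrunk toward its diagonal,
`(1 - lambda) S + lambda diag(S)`, with a Ledoit–Wolf-style analytic
intensity (estimated variance of the off-diagonal covariances over
their squared magnitudes) unless supplied. The result is checked for
positive definiteness and, in the rare ill-conditioned case, the
intensity is raised in 0.05 steps until a Cholesky factorization
succeeds. The scale is df-aware: passing the GLM residual df avoids
underestimating the noise variance after a ~200-column model fit.

`compute_rdm()` assembles all pairwise LDC values into the 72 x 72 RDM
through a single cross-run Gram matrix (the pair distance is
`G_ii + G_jj - G_ij - G_ji`), divides by the voxel count when
`normalize = TRUE` so ROIs of different size are comparable, and
symmetrizes. `collapse_rdm()` averages distractor pairs into the
simplified 24 x 24 task x step RDM.

## The decomposition model

`build_model_rdms()` codes every condition pair with:

* `room` — 1 if the cued tasks' rooms differ;
* `task` — 1 if the cued tasks differ (so `room = 1` implies `task = 1`,
  and the two coefficients are the *different-room vs same-room* and
  *different-task vs same-task* contrasts directly);
* `step` — absolute step-position difference (0–3), entering linearly;
* `visual` — 1, 0.5 or 0 for zero, one or two display tasks shared
  between the pair ({cued, distractor} set overlap), removing the
  visual confound of shared search-array items;
* the intercept — *item* representation, because every included pair
  differs in target item by construction.

The include mask drops the diagonal and the *matched-item* cells (same
cued task and step, different distractor) — the only off-diagonal pairs
sharing a target item — so the intercept is interpretable. Of the 2556
unique pairs, 2484 remain.

`fit_decomposition()` solves this by equal-weight OLS on the unique
upper-triangle included cells. Cell errors are correlated (cells share
conditions), so the per-fit standard errors are descriptive; inference
happens across subjects with one-tailed one-sample t tests and BH-FDR,
exactly as the group layer (`group_ttest()`, `fdr_bh()`) implements.
`fit_step_stratified()` refits within cells at exactly one, two or three
steps apart (dropping the step regressor, which is constant there) to
check that task representation does not depend on temporal separation.
`build_rt_rdm()` supplies the cross-validated reaction-time covariate —
signed condition RT differences of one run times those of the other —
which has zero expectation without a true RT difference; condition RT is
the mean correct-trial RT (`condition_mean_rt()`).

## The synthetic generator

`plant_condition_patterns()` builds condition means as a linear sum of
components along mutually orthonormal random directions:

* per-item vectors (`g_item`), per-task vectors (`g_task`), per-room
  vectors (`g_room`);
* a *cumulative* step code `w(k)` summing orthonormal increments, the
  unique simple construction making squared distance exactly
  `g_step^2 |i - j|` — linear in step difference, matching the fitted
  slope model;
* a display component `(a_cued + a_distractor) / sqrt(2)` from per-task
  display vectors. Display content at the condition level is defined by
  *which two tasks* contribute items (the wrong-step distractors vary
  trial to trial), so the component lives at task granularity; squared
  distance then falls by `g_vis^2` per shared display task — exactly
  `2 g_vis^2` times the visual-difference coding.

Every magnitude therefore maps to a closed-form coefficient
(`expected_decomposition()`): intercept `2 g_item^2`, room
`2 g_room^2`, task `2 g_task^2`, step slope `g_step^2`, visual
`2 g_vis^2`, divided by the voxel count for normalized RDMs and by the
marginal noise variance for noise-normalized (Mahalanobis) units.

`simulate_run_bold()` is the forward model of the event GLM: each
condition's onset-plus-epoch regressor times its mean pattern, plus a
run-specific pattern perturbation (`noise_sd`, independent between
runs), low-frequency discrete-cosine drift (`drift_amplitude`), and
AR(1) temporal noise (`ar_rho`, default 0.3; `ar_sd`). Defaults:
160 voxels on a 20^3 grid of 2 mm voxels (matching the acquisition
resolution), TR = 1.373 s.

Two modeling mismatches are deliberate and worth knowing about:

* The GLM is OLS without prewhitening while the default temporal noise
  is AR(1), and the 1/128 Hz filter removes part of the AR(1)
  low-frequency power. The residual-based noise normalizer then sits
  below the marginal noise variance, scaling all fitted coefficients up
  by a common design-dependent factor (~1.1–1.2 at default settings).
  The generator makes this quantifiable rather than hiding it; the
  parameter-recovery test is planted with white noise (`ar_rho = 0`),
  where the closed-form expectation is exact.
* The plug-in inverse of an estimated covariance adds a small
  (order voxels/df) multiplicative inflation; with the shrinkage used
  here it stays within a few percent at the default sizes.

`simulate_behavior()` emulates the behavioural signatures of the
paradigm: first-array slowing (default +250 ms on a 770 ms base, so first
responses fall around 0.9–1.1 s and later responses around 0.7–0.9 s,
typical for this paradigm), a small RT increase per step, error rates growing across steps,
and rare lapse episodes (rate 0.0132, i.e. ~0.95 flagged episodes per
72-episode participant) whose error rate (0.8) makes them reliably
exceed the >25% flagging rule. Errors fall into the four observed
categories (wrong step, wrong task, wrong both, missed). RTs are
independent of the planted patterns, which is what the RT-covariate
null tests require.

What the generator does **not** emulate: HRF shape variability across
voxels or subjects, motion and distortion, spatially correlated noise,
nonlinear BOLD superposition, and behavioural-neural coupling. Passing
tests therefore demonstrate correctness of the estimators under the
stated generative assumptions, not robustness to everything real data
can do.

A simulated subject whose error episodes eliminate *all* episodes of
some combination in a run has inestimable conditions; `run_pipeline()`
replaces such subjects (next seed), mirroring the exclusion of
participants without correct episodes for every combination.

## Searchlight

`sphere_neighborhoods()` enumerates, for every in-mask voxel, the voxels
within 10 mm (inclusive, through the affine, so anisotropic voxels are
handled in millimetres). `searchlight_decomposition_maps()` repeats the
full ROI analysis per sphere — noise covariance from the sphere's
residuals, 72 x 72 LDC RDM, decomposition — and writes each coefficient
to the center voxel. Spheres below 10 voxels (the minimum keeping the
discriminant estimable; the boundary behaviour is otherwise
unspecified) produce missing values, never zeros. `smooth_volume()`
applies a separable Gaussian (sigma = FWHM / 2.355 per axis in mm) with
half-sample reflection at the volume boundary — preserving constants
and, for all-finite maps, total mass — and renormalizes kernel weights
around missing values so they do not leak.

## Group inference

`rm_anova_trends()` implements the one-way repeated-measures ANOVA with
Greenhouse–Geisser correction (epsilon from the double-centered
within-subject covariance, bounded to `[1/(k-1), 1]`, applied to the
omnibus test only) and linear/quadratic trend contrasts with the
standard integer weights for four equally spaced levels (-3, -1, 1, 3
and 1, -1, -1, 1); one-df contrasts need no sphericity correction.
`rm_anova_2w()` covers the 2 x 4 network-by-information design with
per-effect error terms and epsilons. Effect sizes are partial
eta-squared for ANOVAs and Cohen's d for t tests; multiplicity is
handled by Benjamini–Hochberg FDR at 0.05.

## Problem sizes in the test suite

The test suite exercises the pipeline at desk scale: full-length single
runs (~1690 s, 1229 scans) everywhere the design structure matters;
45–160 voxel ROIs; 20 simulated subjects on the 20^3 grid for parameter
recovery; 50 subjects for the null calibration of the LDC; 250 draws
for estimator null checks; 2000 replications for FDR and t-test
calibration; 12^3 volumes for searchlight localization. These sizes
were chosen so every statistical check has the power it needs while the
whole suite stays comfortably runnable on a laptop.

## Known limitations

* OLS without prewhitening (see above); residuals are exposed so users
  can model autocorrelation downstream.
* The decomposition treats RDM cells as exchangeable observations
  within subject; dependence between cells is handled only at the
  group level.
* The efficiency criterion for order selection uses episode-level task
  regressors; other parameterizations of the efficiency computation are
  possible and may rank candidates differently.
* No surface-based searchlights, no permutation/cluster inference, no
  slice-timing-aware microtime offsets.
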