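---
title: "Low-dimensional trajectory analysis of task-evoked brain activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-dimensional trajectory analysis of task-evoked brain activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotraj)
```

# The scientific problem

When working-memory load increases (a 2-back versus a 1-back task), the
whole-brain pattern of task-evoked BOLD activity traverses a larger
region of its state space: the low-dimensional trajectory of brain
activity *expands*. Local perturbation of a task-relevant cortical site
(continuous theta-burst TMS over the intraparietal sulcus, iPS)
reorganizes this geometry far more than perturbation of a
task-irrelevant control site (S1). `neurotraj` implements the full
analysis chain needed to quantify such effects — trial-locked response
estimation, manifold embedding, trajectory geometry, quality control,
and inference — together with a synthetic-data generator that plants
known trajectory geometry so every stage can be validated against
ground truth.

# Task model

A session consists of runs of counterbalanced 1-back/2-back blocks
interleaved with rest. Each 60-s task block opens with a 2-s cue
followed by 13 trials (0.5-s stimulus, jittered inter-trial fixation in
[1.5, 10] s). The long variant (4 runs x 3 blocks) and the short
variant (6 runs x 2 blocks) both deliver exactly 78 trials per load
condition per session. Per-run duration is derived from the components:
155 s for the short variant (3 + 60 + 25 + 60 + 7), 253 s for the long
variant.

Two arithmetic constraints deserve note. First, 13 trials with
independent uniform ITIs (mean 5.75 s) cannot fit the 51.5 s a 60-s
block leaves after cue and stimuli; the generator therefore draws ITIs
uniformly on [1.5, 10] s and rescales them affinely above the 1.5-s
floor so each block is filled exactly. The resulting ITIs stay inside
the nominal range but are uniform on a narrower effective interval.
Second, a commonly quoted 236-s long-run total is not reconstructible
from any combination of the printed components; we derive 253 s and do
not force the quoted figure.

Targets ("repeats") are planted 2–4 per block, never earlier than
trial n+1 and never adjacent, which keeps every 2-back target
well-defined.

# Synthetic data with analytic ground truth

The generator plants a three-dimensional latent loop (a smooth closed
curve with zero centroid) sampled at one anchor per trial, in trial
order. Load expansion is a radial scaling of the whole loop about the
origin by the factor `E`: latent arc length is then *exactly* linear in
`E`, so the planted 2-back/1-back length ratio is analytic. The 2-back
anchors sit at half-step phase offsets of the same loop — load expands
activity along the same latent modes, consistent with intertwined load
conditions in one embedding space. Incorrect trials shrink radially by
`accuracy_shrink` (default 0.4), reproducing the correct > incorrect
length ordering.

Each trial contributes a 1-s neural epoch at its anchor value; the
latent courses are convolved with the canonical HRF on a 0.1-s grid,
mixed into 333 regions through a random orthonormal loading matrix, and
corrupted with AR(1) Gaussian noise (coefficient 0.4, the simplest
model of BOLD autocorrelation). Because every step from latent anchors
to fitted responses is linear, the planted ratio propagates exactly
through estimation — making the nonlinear embedding the only stage
whose fidelity is genuinely at stake.

## Noise calibration

`target_snr` is defined on the quantity the pipeline actually analyzes:
the ratio of the RMS amplitude of noiseless estimated single-trial
responses to the RMS of their estimation error. Calibration is
empirical — probe GLMs on unit-variance AR(1) noise — so design
conditioning and noise autocorrelation are priced in automatically.

By default the reference is the *group-mean* series
(`snr_reference = "group"`): the per-participant noise is inflated by
`sqrt(n)` so that the n-participant average sits at the target SNR.
Rationale: group-level embeddings of real data concatenate
participants, so each embedded point carries single-participant noise;
our desk-scale pipeline averages responses before embedding instead
(dense spectral embeddings of ~24,000 points are out of reach without
landmark approximations, which are out of scope). Group-referencing
keeps the noise floor of the embedded point cloud at the stated SNR.
At n = 17 and `target_snr = 2` the implied single-trial,
single-participant SNR is about 0.5 — realistic for single-trial fMRI
response estimates.

# Response estimation

Each trial is modeled by three regressors: stimulus stick convolved
with the canonical double-gamma HRF (gamma shapes 6 and 16, unit
scales, undershoot ratio 6, unit peak normalization) plus its delay
derivative (1-s finite onset shift) and dispersion derivative (0.01
scale change). Convolution runs on a 0.1-s grid so jittered onsets are
exact, then resamples at TR = 1 s. All trials enter one GLM per session
(beta-series style) with per-run intercepts; if short ITIs made the
joint design ill-conditioned (condition number above 1e6) the fit falls
back to least-squares-separate estimation — in practice the jittered
designs here have condition numbers around a few hundred.

Fitted responses are evaluated at 1, 2, ..., 9 s after onset (nine
samples at TR = 1 s). The onset instant itself is excluded: every basis
function vanishes identically at lag zero, so including it would pin
all trials to a single duplicated point in state space and break the
adaptive kernel bandwidth. Trials are concatenated in condition,
accuracy, onset order; 78 trials x 9 samples x 2 conditions give the
1,404-point group series the embedding consumes.

# The diffusion-potential embedding

The embedding is implemented from scratch:

1. **Alpha-decay kernel.** Euclidean distances between time samples
   (across region features) enter
   `K_ij = 1/2 exp(-(d_ij/eps_i)^alpha) + 1/2 exp(-(d_ij/eps_j)^alpha)`
   with `eps_i` the distance to the `knn`-th neighbor (defaults
   `alpha = 35`, `knn = 10`). The large exponent makes the kernel
   nearly binary around each point's `knn` neighborhood.
2. **Diffusion operator.** Row normalization gives random-walk
   probabilities `P`; the symmetric conjugate `D^{1/2} P D^{-1/2}`
   supplies a full eigendecomposition reused everywhere downstream.
3. **Diffusion time by von Neumann entropy.** `H(t)` is the entropy of
   the normalized powered spectrum; the selected `t` is the knee of
   `H(t)` on 1..100 by maximum perpendicular distance from the chord —
   deterministic and parameter-free among elbow rules. On the synthetic
   group series the knee lands near t = 19–21. A fixed `t` (e.g. the
   group value 32 used in comparable analyses) can be supplied instead;
   measured ratios change by only a few percent.
4. **Potential distances.** `U_ij` is the Euclidean distance between
   `log(P^t + 1e-12)` rows. Connectivity is checked first; truly
   disconnected graphs are refused rather than papered over by the log
   floor.
5. **Metric MDS.** Classical (double-centering) initialization followed
   by SMACOF stress majorization of raw stress. Majorization guarantees
   monotone stress decrease; iterations stop at a relative decrease
   below 1e-6 or at `mds_max_iter` (default 50; on the group fixtures
   the measured ratios at 30, 50, and 100 iterations agree to three
   decimals). Output dimensions are ordered by variance; trajectories
   use the top three of five.

Spatial weights — the engagement of each region with each embedding
dimension — are computed as the Pearson correlation between the
region's concatenated response course and the coordinate course. This
is a reconstruction chosen as the simplest projection with the right
invariances; it is not uniquely determined by the quantity it
visualizes.

# Trajectory geometry and inference

Trajectory length is the summed Euclidean distance over consecutive
embedded points (top three dimensions); the expansion ratio is the
2-back/1-back length quotient within one embedding space (cross-space
comparisons are refused). Group-individual distance is the index-matched
summed distance over the shared trial grid, with linear resampling only
when counts differ. Load scaling regresses 2-back distances on 1-back
distances across participants.

The inferential battery wraps the standard tools: two-sided paired t,
within-subject ANOVA by `aov` error strata (no sphericity correction by
default), Pearson correlation, Benjamini-Hochberg step-up FDR, and the
Dunn-Clark z for dependent non-overlapping correlations — the standard
construction for comparing two variable pairs measured on the same
subjects, here the trajectory-length/behavior correlations of two
sessions. Its null covariance uses the four cross-correlations of the
involved variables. All tests are exercised under their nulls at
n = 17 in the acceptance suite; the z-test is asymptotic but calibrates
within Monte-Carlo error at this n.

# Spectral-kurtosis quality control

Sharp edges or discontinuities in the trial-concatenated convolved
stimulus series are screened by spectral kurtosis:
`SK(f) = <P^2>/<P>^2 - 2` over short-time Hann frames (64 samples, 50%
overlap), which is ~0 for stationary Gaussian signals, -1 for a pure
line, and large at transients. Frequencies with
`SK > 3 sqrt(4/M)` mark transient content; a frame is flagged when its
mean normalized power excess over those `m` frequencies exceeds
`3/sqrt(m)` (three null standard deviations of that frame score). Bins
holding a negligible share of the average power are excluded — the HRF
is a strong lowpass, and near-empty bins otherwise produce spurious SK
values. Every setting is a documented reconstruction (only the
statistic itself is given by the source methodology) and is exposed as
an argument. Sessions pass below 7% flagged frames; the trial-window
truncation seams are precisely what this step quantifies, and the
untruncated continuous regressor passes with margin.

# What the synthetic validation does and does not show

The generator emulates: the exact n-back block/trial arithmetic,
trial-locked HRF dynamics with latency/dispersion content, AR(1)
temporal autocorrelation, planted condition-dependent expansion and
accuracy shrink, participant gain variability, and a plantable
trajectory-behavior correlation. It does not emulate spatially
correlated noise, motion or physiological artifacts, biophysical BOLD
nonlinearity, or real parcel covariance — passing tests certify the
pipeline's computational fidelity, not robustness to those real-data
features.

One genuine limitation surfaced by the validation: the adaptive
per-point bandwidth makes the kernel locally scale-free, so two
trajectories that differ *only* by a global scale factor produce nearly
identical diffusion geometry; the ambient scale enters the embedding
only through the absolute noise floor, and log-potential distances
grow with diffusion steps rather than ambient length. Planted
expansion factors are therefore recovered *compressed*: at the study
conditions, a planted 1.5 is estimated near 1.24, a planted 3 near
2.2, and a planted 7 near 4 (medians over 10 cohort seeds). The
session *ordering* of ratios (planted 1.3 < 1.5 < 7.3) is recovered in
9 of 10 seeds; the closest session pair compresses to medians near
1.13 versus 1.21 and can occasionally tie. Absolute expansion
ratios from this family of embeddings should be read as qualitative
(ordinal) effect sizes, not calibrated multipliers; the response-space
(pre-embedding) ratio, which the linear estimation chain preserves
essentially unbiased, is the calibrated alternative this package also
reports.

# Problem sizes and numerical choices

The validation experiments use the study-scale conditions end to end:
17 participants, 78 trials per condition, 333 regions, group series of
1,404 points. Dense eigendecompositions at n = 1404 run in about a
second; a full cohort simulation, estimation, and embedding takes
roughly ten seconds, and the headline recovery experiment (six planted
conditions x 10 seeds) is the dominant cost of the acceptance suite.
Degenerate inputs are refused loudly everywhere: zero kernel
bandwidths (duplicate points), disconnected affinity graphs, constant
entropy curves, rank-deficient designs, unbalanced ANOVA tables,
constant QC signals.
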