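# neurotraj

Low-dimensional trajectories of task-evoked brain activity: simulation,
estimation, embedding, geometry, and inference.

## What this package is for

Increasing working-memory load (2-back versus 1-back) expands the
trajectory that whole-brain activity traces through its state space,
and perturbing a task-relevant cortical site reshapes that geometry.
`neurotraj` implements the complete analysis chain used to quantify
such effects on parcellated BOLD time series, and a synthetic-data
generator with *analytic* ground truth so that every stage can be
validated:

- **Task design** — n-back session schedules (counterbalanced 60-s
  blocks, 2-s cues, 13 trials per block, jittered 1.5–10-s ITIs;
  exactly 78 trials per load condition per session), BIDS-style events
  TSV round-tripping.
- **Synthetic BOLD** — latent loop trajectories with planted
  condition-dependent expansion and accuracy shrink, mixed into 333
  regions, HRF-convolved, with AR(1) noise calibrated to a target
  trial-level SNR.
- **Response estimation** — trial-wise GLM with the informed basis set
  (canonical double-gamma HRF plus delay and dispersion derivatives),
  per-run intercepts, 9-s trial response windows, group concatenation.
- **Diffusion-potential embedding** (from scratch) — alpha-decay
  kernel with adaptive knn bandwidth (`alpha = 35`, `knn = 10`),
  row-stochastic diffusion operator, diffusion time at the von Neumann
  entropy knee, potential distances
  `U_ij = ||log(P^t_i.) - log(P^t_j.)||`, metric MDS by SMACOF stress
  majorization, per-dimension variance fractions, region spatial
  weights.
- **Trajectory geometry** — lengths, 2-back/1-back expansion ratios,
  group–individual summed distances, load scaling,
  trajectory–behavior correlations.
- **QC** — spectral-kurtosis screening of convolved stimulus series
  for sharp edges/discontinuities (pass criterion < 7% flagged).
- **Inference** — paired t, within-subject ANOVA, Pearson, Dunn–Clark
  z for dependent non-overlapping correlations, Benjamini–Hochberg FDR.

## Worked example

Simulate a 17-participant session with a planted 2-back/1-back
expansion of 3 at trial-level SNR 2, estimate trial responses, embed
the group series, and measure the expansion ratio:

```r
library(neurotraj)

cfg    <- task_config("long", seed = 1)
truth  <- ground_truth(n_regions = 333, expansion_factor = 3,
                       target_snr = 2, seed = 1)
cohort <- simulate_cohort(17, cfg, truth, seed = 1)

design    <- build_design_matrix(cohort$schedule, hrf_basis(),
                                 n_scans = cohort$sessions[[1]]$n_scans)
responses <- lapply(cohort$sessions, function(s)
  fit_trial_responses(s$ts, design, participant = s$participant))
group     <- group_mean_responses(responses)
print(group)
#> response matrix: 1404 samples x 333 regions (TR = 1 s, 9-s window)
#>         correct
#>   1back      78
#>   2back      78

emb <- phate_embed(group)
print(emb)
#> diffusion-potential embedding: 1404 points x 5 dims
#>   t = 20, stress = 8.033e+05
#>   variance fractions: 0.369 0.342 0.250 0.025 0.014

trajs <- extract_trajectories(emb, dims = 3)
expansion_ratio(trajs[["2back.correct"]], trajs[["1back.correct"]])
#> [1] 2.532844
```

The group trajectory is 1,404 embedded points (78 trials x 9 samples x
2 conditions); the diffusion time lands at the entropy knee (t = 20),
the first three dimensions carry ~96% of the retained variance, and
the measured expansion ratio is 2.53 against a planted factor of 3.
Recovered ratios are systematically *compressed*: the adaptive kernel
bandwidth normalizes local scale, so ambient magnification survives the
embedding only partially (orderings across conditions are preserved
robustly; see the methods vignette for the full characterization). The
pre-embedding response-space ratio, in contrast, recovers the planted
factor essentially unbiased.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` (three sessions with planted expansions
1.3 / 1.5 / 7.3), `02_estimate.R`, `03_embed.R`, `04_metrics.R`,
`05_inference.R`, `06_qc.R`, each writing its tables under `results/`.

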