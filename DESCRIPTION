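Package: neurotraj
Title: Low-Dimensional Trajectories of Task-Evoked Brain Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of low-dimensional state-space
    trajectories of task-evoked brain activity under working-memory load
    and local neural perturbation. Provides an n-back task schedule
    generator, a parcellated-BOLD simulator with planted latent
    trajectory geometry, trial-locked response estimation with an
    informed hemodynamic basis set (canonical double-gamma plus delay and
    dispersion derivatives), a from-scratch diffusion-potential manifold
    embedding (alpha-decay kernel, von Neumann entropy diffusion-time
    selection, potential distances, metric MDS by stress majorization),
    trajectory geometry statistics (lengths, expansion ratios,
    group-individual distances, load scaling), spectral-kurtosis
    stimulus quality control, and the accompanying inferential battery
    (paired t, repeated-measures ANOVA, Pearson, Dunn-Clark comparison
    of dependent correlations, Benjamini-Hochberg FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
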