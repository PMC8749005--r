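#!/usr/bin/env Rscript
# Stage 2: trial-locked response estimation.
#
# Re-simulates the cohort deterministically from the stage-1 seed,
# fits the trial-wise GLM (canonical HRF + delay and dispersion
# derivatives, per-run intercepts), and summarizes the estimated
# responses: per-participant trajectory lengths in region space and the
# response-space 2-back/1-back ratio, which should sit near the planted
# factor before any embedding.

suppressPackageStartupMessages(library(neurotraj))
seed <- 20260920L
out <- "results"
dir.create(out, showWarnings = FALSE)

sessions <- c(baseline = 1.3, S1 = 1.5, iPS = 7.3)
rows <- list()
for (i in seq_along(sessions)) {
  sess <- names(sessions)[i]
  cfg <- task_config("long", seed = seed + 1000L * i)
  truth <- ground_truth(n_regions = 333, expansion_factor = sessions[[i]],
                        target_snr = 2, seed = seed)
  cohort <- simulate_cohort(17, cfg, truth, seed = seed + 1000L * i,
                            session_label = sess)
  design <- build_design_matrix(cohort$schedule, hrf_basis(),
                                n_scans = cohort$sessions[[1]]$n_scans)
  responses <- lapply(cohort$sessions, function(s) {
    fit_trial_responses(s$ts, design, session = sess,
                        participant = s$participant)
  })
  group <- group_mean_responses(responses)
  len <- function(rm, cond) trajectory_length(
    response_cell(rm, cond)$values, dims = ncol(rm$values))
  ratio_group <- len(group, "2back") / len(group, "1back")
  ratio_part <- vapply(responses, function(r) {
    len(r, "2back") / len(r, "1back")
  }, numeric(1))
  rows[[sess]] <- data.frame(
    session = sess, planted = sessions[[i]],
    response_space_ratio_group = ratio_group,
    response_space_ratio_participant_mean = mean(ratio_part),
    design_condition_number = design$kappa)
  cat(sprintf(
    "%-8s planted %.1f | response-space ratio: group %.3f, participant mean %.3f\n",
    sess, sessions[[i]], ratio_group, mean(ratio_part)))
}
write.csv(do.call(rbind, rows),
          file.path(out, "02_response_estimation.csv"), row.names = FALSE)
cat("\nThe linear estimation chain approximately preserves the planted\n")
cat("ratios (noise inflates the low-load denominator at large factors);\n")
cat("summary written to results/02_response_estimation.csv.\n")
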