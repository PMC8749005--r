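#!/usr/bin/env Rscript
# Stage 5: inferential battery.
#
# Participant-level trajectory lengths (response space, 2-back correct)
# across the three sessions: paired t-tests with BH-FDR, a
# repeated-measures ANOVA on session, trajectory-behavior correlations
# per session, and the Dunn-Clark comparison of the baseline and iPS
# correlations.

suppressPackageStartupMessages(library(neurotraj))
seed <- 20260920L
out <- "results"
dir.create(out, showWarnings = FALSE)

sessions <- c(baseline = 1.3, S1 = 1.5, iPS = 7.3)
lengths <- list()
behav <- list()
for (i in seq_along(sessions)) {
  sess <- names(sessions)[i]
  cfg <- task_config("long", seed = seed + 1000L * i)
  truth <- ground_truth(n_regions = 333, expansion_factor = sessions[[i]],
                        target_snr = 2, seed = seed)
  # planted trajectory-behavior association: positive at baseline and
  # S1, negative after task-relevant perturbation (iPS)
  cohort <- simulate_cohort(17, cfg, truth, seed = seed + 1000L * i,
                            behavior_cor = ifelse(sess == "iPS", -0.5, 0.5),
                            session_label = sess)
  design <- build_design_matrix(cohort$schedule, hrf_basis(),
                                n_scans = cohort$sessions[[1]]$n_scans)
  lengths[[sess]] <- vapply(cohort$sessions, function(s) {
    r <- fit_trial_responses(s$ts, design, participant = s$participant)
    cell <- response_cell(r, "2back")
    trajectory_length(cell$values, dims = ncol(cell$values))
  }, numeric(1))
  behav[[sess]] <- cohort$behavior$accuracy_2back
}

stats_out <- list()
pairs <- combn(names(sessions), 2, simplify = FALSE)
pvec <- vapply(pairs, function(pr) {
  paired_t(lengths[[pr[2]]], lengths[[pr[1]]])$p
}, numeric(1))
padj <- bh_fdr(pvec)
for (k in seq_along(pairs)) {
  res <- paired_t(lengths[[pairs[[k]][2]]], lengths[[pairs[[k]][1]]])
  cat(sprintf("paired t %s > %s: t = %.2f, p_FDR = %.3g\n",
              pairs[[k]][2], pairs[[k]][1], res$statistic, padj[k]))
  stats_out[[paste(pairs[[k]], collapse = "_vs_")]] <-
    list(t = res$statistic, df = res$df, p = res$p, p_fdr = padj[k])
}
an <- rm_anova(do.call(cbind, lengths))
cat(sprintf("rm-ANOVA session effect: F(%d,%d) = %.2f, p = %.3g\n",
            an$df[1], an$df[2], an$statistic, an$p))
stats_out$rm_anova <- list(F = an$statistic, df = an$df, p = an$p)

for (sess in names(sessions)) {
  ba <- behavior_association(lengths[[sess]], behav[[sess]])
  cat(sprintf("length-accuracy correlation, %s: r = %.2f, p = %.3g\n",
              sess, ba$r, ba$p))
  stats_out[[paste0("behavior_", sess)]] <- ba
}
dc <- compare_dependent_correlations_data(
  lengths[["baseline"]], behav[["baseline"]],
  lengths[["iPS"]], behav[["iPS"]])
cat(sprintf("Dunn-Clark baseline vs iPS: z = %.2f, p = %.3g\n",
            dc$statistic, dc$p))
stats_out$dunn_clark_baseline_vs_iPS <- list(z = dc$statistic, p = dc$p)

jsonlite::write_json(stats_out, file.path(out, "05_inference.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nStatistics written to results/05_inference.json.\n")
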