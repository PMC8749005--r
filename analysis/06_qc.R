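#!/usr/bin/env Rscript
# Stage 6: stimulus quality control.
#
# Spectral-kurtosis screening of the trial-concatenated convolved
# stimulus series for each session's schedule: the flagged fraction
# estimates how much of the series carries sharp edges or
# discontinuities (window truncation seams); sessions pass below 7%.

suppressPackageStartupMessages(library(neurotraj))
seed <- 20260920L
out <- "results"
dir.create(out, showWarnings = FALSE)

sessions <- c(baseline = 1.3, S1 = 1.5, iPS = 7.3)
series <- lapply(seq_along(sessions), function(i) {
  stimulus_series(generate_schedule(
    task_config("long", seed = seed + 1000L * i)))
})
names(series) <- names(sessions)
report <- edge_fraction_report(series)
print(report, row.names = FALSE)
jsonlite::write_json(report, file.path(out, "06_qc.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("\n%d of %d sessions pass the < 7%% sharp-edge criterion;\n",
            sum(report$pass), nrow(report)))
cat("report written to results/06_qc.json.\n")
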