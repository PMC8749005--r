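#' Configure an end-to-end pipeline run
#'
#' One validated configuration object drives simulation, response
#' estimation, embedding, trajectory metrics, QC, and inference; the
#' master seed propagates to every stochastic stage, so a re-run with
#' the same config reproduces all numeric outputs.
#'
#' @param participants cohort size (default 17).
#' @param sessions named numeric vector: planted 2-back/1-back expansion
#'   factor per session (default `c(baseline = 1.3, S1 = 1.5,
#'   iPS = 7.3)`, the study's session-wise expansion ordering).
#' @param variant task variant (default `"long"`).
#' @param n_runs runs per session; `NULL` for the variant default.
#' @param n_regions parcel count (default 333).
#' @param target_snr trial-level SNR of the simulation (default 2).
#' @param accuracy_rate trial-level probability correct (default 1).
#' @param knn,alpha,t,n_dims embedding parameters (defaults 10, 35,
#'   `"auto"`, 5).
#' @param community_table_path optional TSV path for community
#'   summaries.
#' @param output_dir where `run_pipeline()` writes its artifacts.
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(participants = 17,
                            sessions = c(baseline = 1.3, S1 = 1.5,
                                         iPS = 7.3),
                            variant = "long", n_runs = NULL,
                            n_regions = 333,
                            target_snr = 2, accuracy_rate = 1,
                            knn = 10, alpha = 35, t = "auto", n_dims = 5,
                            community_table_path = NULL,
                            output_dir = tempfile("neurotraj_run_"),
                            seed = 1L) {
  if (participants < 1) stopf("participants must be >= 1")
  if (is.null(names(sessions)) || any(!nzchar(names(sessions)))) {
    stopf("sessions must be a named vector of expansion factors")
  }
  if (any(sessions <= 0)) stopf("expansion factors must be > 0")
  if (!is.null(community_table_path) && !file.exists(community_table_path)) {
    stopf("community table not found: %s", community_table_path)
  }
  structure(list(participants = as.integer(participants),
                 sessions = sessions, variant = variant,
                 n_runs = n_runs,
                 n_regions = as.integer(n_regions),
                 target_snr = target_snr, accuracy_rate = accuracy_rate,
                 knn = knn, alpha = alpha, t = t, n_dims = n_dims,
                 community_table_path = community_table_path,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Simulate one session's cohort, fit responses, and embed the group
# mean; returns everything downstream stages need.
run_session_stage <- function(cfg, session, expansion, seed,
                              mds_max_iter = 50) {
  config <- task_config(cfg$variant, n_runs = cfg$n_runs, seed = seed)
  truth <- ground_truth(n_regions = cfg$n_regions,
                        expansion_factor = expansion,
                        target_snr = cfg$target_snr, seed = cfg$seed)
  cohort <- simulate_cohort(cfg$participants, config, truth, seed = seed,
                            accuracy_rate = cfg$accuracy_rate,
                            session_label = session)
  basis <- hrf_basis()
  design <- build_design_matrix(cohort$schedule, basis,
                                n_scans = cohort$sessions[[1]]$n_scans)
  responses <- lapply(cohort$sessions, function(s) {
    fit_trial_responses(s$ts, design, session = session,
                        participant = s$participant)
  })
  group <- group_mean_responses(responses)
  embedding <- phate_embed(group, n_dims = cfg$n_dims, knn = cfg$knn,
                           alpha = cfg$alpha, t = cfg$t,
                           mds_max_iter = mds_max_iter)
  list(session = session, cohort = cohort, design = design,
       responses = responses, group = group, embedding = embedding)
}

#' Estimate the load expansion ratio on one simulated session cohort
#'
#' The end-to-end recovery experiment for a single session: simulates a
#' cohort at the planted expansion factor, estimates trial-locked
#' responses, embeds the group-mean responses, and returns the
#' 2-back/1-back trajectory-length ratio in the top three embedding
#' dimensions alongside the planted value.
#'
#' @param expansion planted 2-back/1-back latent length ratio.
#' @param seed integer seed for schedule and noise.
#' @param participants cohort size (default 17).
#' @param n_regions parcel count (default 333).
#' @param target_snr trial-level SNR of the group series (default 2).
#' @param variant task variant (default `"long"`).
#' @param knn,alpha,t embedding parameters (defaults 10, 35, `"auto"`).
#' @param mds_max_iter majorization cap (default 50).
#' @return List with `ratio` (estimated), `planted`, `length_1back`,
#'   `length_2back`, `t_selected`, and the `embedding`.
#' @export
estimate_expansion_ratio <- function(expansion, seed,
                                     participants = 17, n_regions = 333,
                                     target_snr = 2, variant = "long",
                                     knn = 10, alpha = 35, t = "auto",
                                     mds_max_iter = 50) {
  cfg <- pipeline_config(participants = participants,
                         sessions = c(session = expansion),
                         variant = variant, n_regions = n_regions,
                         target_snr = target_snr, knn = knn,
                         alpha = alpha, t = t, seed = as.integer(seed))
  stage <- run_session_stage(cfg, "session", expansion, seed = cfg$seed,
                             mds_max_iter = mds_max_iter)
  trajs <- extract_trajectories(stage$embedding, dims = 3)
  len1 <- trajectory_length(trajs[["1back.correct"]])
  len2 <- trajectory_length(trajs[["2back.correct"]])
  list(ratio = len2 / len1, planted = expansion,
       length_1back = len1, length_2back = len2,
       t_selected = stage$embedding$t_selected,
       embedding = stage$embedding)
}

# Per-participant trajectory lengths in response (region) space.
participant_lengths <- function(responses, condition,
                                accuracy = "correct", dims = Inf) {
  vapply(responses, function(r) {
    cell <- response_cell(r, condition = condition, accuracy = accuracy)
    trajectory_length(cell$values, dims = min(dims, ncol(cell$values)))
  }, numeric(1))
}

#' Run the full analysis pipeline on synthetic data
#'
#' For each session: simulates the cohort at the planted expansion
#' factor, estimates trial-locked responses, embeds the group-mean
#' responses, and measures trajectory lengths and the 2-back/1-back
#' expansion ratio. Across sessions it runs the inferential battery
#' (paired t-tests on participant-level lengths with BH-FDR,
#' repeated-measures ANOVA on the load contrast, trajectory-behavior
#' correlations and their Dunn-Clark comparison), the spectral-kurtosis
#' stimulus QC, and writes `metrics.csv`, `stats.json`, `qc.json`,
#' per-session embedding CSVs, and a run manifest under
#' `config$output_dir`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a results bundle: list with `metrics`, `stats`,
#'   `qc`, `embeddings`, `manifest`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- names(config$sessions)
  stages <- list()
  metrics <- list()
  qc_series <- list()
  lengths_2b <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[i]
    stage <- tryCatch(
      run_session_stage(config, s, config$sessions[[i]],
                        seed = config$seed + 1000L * i),
      error = function(e) stopf("stage '%s' failed: %s", s, conditionMessage(e)))
    stages[[s]] <- stage
    trajs <- extract_trajectories(stage$embedding, dims = 3)
    len1 <- trajectory_length(trajs[["1back.correct"]])
    len2 <- trajectory_length(trajs[["2back.correct"]])
    ratio <- expansion_ratio(trajs[["2back.correct"]], trajs[["1back.correct"]])
    metrics[[s]] <- data.frame(
      session = s, planted_expansion = config$sessions[[i]],
      length_1back = len1, length_2back = len2,
      expansion_ratio = ratio,
      t_selected = stage$embedding$t_selected,
      var_dim1 = stage$embedding$variance_fraction[1],
      stringsAsFactors = FALSE)
    qc_series[[s]] <- stimulus_series(stage$cohort$schedule)
    lengths_2b[[s]] <- participant_lengths(stage$responses, "2back")
    write_embedding(stage$embedding,
                    file.path(config$output_dir,
                              sprintf("embedding_%s.csv", s)))
  }
  metrics <- do.call(rbind, metrics)
  utils::write.csv(metrics, file.path(config$output_dir, "metrics.csv"),
                   row.names = FALSE)

  qc <- edge_fraction_report(qc_series)
  jsonlite::write_json(qc, file.path(config$output_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # inferential battery on participant-level 2-back lengths
  stats_out <- list()
  if (length(sessions) >= 2 && config$participants >= 2) {
    pairs <- utils::combn(sessions, 2, simplify = FALSE)
    pvec <- numeric(0)
    tests <- list()
    for (pr in pairs) {
      res <- paired_t(lengths_2b[[pr[2]]], lengths_2b[[pr[1]]])
      tests[[paste(pr[2], ">", pr[1])]] <-
        list(t = res$statistic, df = res$df, p = res$p)
      pvec <- c(pvec, res$p)
    }
    adj <- bh_fdr(pvec)
    for (k in seq_along(tests)) tests[[k]]$p_fdr <- adj[k]
    stats_out$paired_t_2back_length <- tests
    if (length(sessions) >= 2 && config$participants >= 3) {
      mat <- do.call(cbind, lengths_2b)
      an <- rm_anova(mat)
      stats_out$rm_anova_session <- list(F = an$statistic,
                                         df = an$df, p = an$p)
    }
  }
  # trajectory-behavior associations (participant gains carry the
  # planted correlation)
  behav <- stages[[1]]$cohort$behavior
  if (!is.null(behav) && config$participants >= 4) {
    assoc <- lapply(sessions, function(s) {
      b <- stages[[s]]$cohort$behavior
      behavior_association(lengths_2b[[s]], b$accuracy_2back)
    })
    names(assoc) <- sessions
    stats_out$behavior_association <- assoc
    if (all(c("baseline", "iPS") %in% sessions) && config$participants >= 10) {
      cmp <- compare_dependent_correlations_data(
        lengths_2b[["baseline"]],
        stages[["baseline"]]$cohort$behavior$accuracy_2back,
        lengths_2b[["iPS"]],
        stages[["iPS"]]$cohort$behavior$accuracy_2back)
      stats_out$dependent_correlation_baseline_vs_iPS <-
        list(z = cmp$statistic, p = cmp$p)
    }
  }
  jsonlite::write_json(stats_out, file.path(config$output_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # community summary when a table is supplied
  community <- NULL
  if (!is.null(config$community_table_path)) {
    tab <- read_community_table(config$community_table_path)
    community <- community_summary(
      stages[[1]]$embedding$spatial_weights, tab)
    utils::write.csv(community,
                     file.path(config$output_dir, "community_summary.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("neurotraj")),
    r_version = R.version.string,
    seed = config$seed,
    participants = config$participants,
    sessions = as.list(config$sessions),
    variant = config$variant, n_regions = config$n_regions,
    target_snr = config$target_snr, accuracy_rate = config$accuracy_rate,
    embedding = list(knn = config$knn, alpha = config$alpha,
                     t = config$t, n_dims = config$n_dims),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metrics = metrics, stats = stats_out, qc = qc,
                 embeddings = lapply(stages, `[[`, "embedding"),
                 community = community, manifest = manifest,
                 stages = stages, output_dir = config$output_dir))
}

#' Community-level summary of spatial weights
#'
#' Mean absolute region weight per network community per embedding
#' dimension.
#'
#' @param weights regions x dimensions matrix from [spatial_weights()].
#' @param communities a community table
#'   (see [read_community_table()]) covering every weighted region.
#' @return data.frame sorted by community with one column per dimension.
#' @export
community_summary <- function(weights, communities) {
  regions <- rownames(weights)
  if (is.null(regions)) regions <- paste0("region", seq_len(nrow(weights)))
  missing <- setdiff(regions, communities$region_id)
  if (length(missing)) {
    stopf("unmapped region(s): %s%s",
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5)
          else "")
  }
  comm <- communities$community[match(regions, communities$region_id)]
  agg <- stats::aggregate(abs(weights), by = list(community = comm), FUN = mean)
  agg[order(agg$community), , drop = FALSE]
}
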