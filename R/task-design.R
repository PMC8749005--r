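#' Configure an n-back session
#'
#' Builds a validated configuration for an n-back working-memory session.
#' Two variants are supported: `"short"` (6 runs of two 60-s task blocks
#' separated by a 25-s rest block, 7-s final fixation, 155 s per run) and
#' `"long"` (4 runs of three 60-s task blocks separated by 30-s rest
#' blocks, 10-s final fixation). Both yield 78 trials per load condition
#' per session with the default 13 trials per block.
#'
#' @param variant `"short"` or `"long"`; sets the per-variant defaults.
#' @param n_runs number of runs; 0 is allowed and yields an empty schedule.
#' @param blocks_per_run task blocks per run.
#' @param trials_per_block trials per task block (default 13).
#' @param block_duration_s task block duration in seconds (default 60).
#' @param rest_duration_s rest block duration between task blocks.
#' @param initial_fixation_s fixation before the first block (default 3).
#' @param cue_duration_s block initiation cue duration (default 2).
#' @param final_fixation_s fixation after the last block.
#' @param stim_duration_s stimulus presentation time (default 0.5).
#' @param iti_range_s two-element range of the jittered inter-trial
#'   fixation, seconds (default `c(1.5, 10)`).
#' @param n_repeats_range range of target ("repeat") trials per block
#'   (default `c(2, 4)`).
#' @param n_stimuli size of the stimulus pool (default 120).
#' @param seed integer seed used by [generate_schedule()].
#' @return A `task_config` list.
#' @export
task_config <- function(variant = c("long", "short"),
                        n_runs = NULL,
                        blocks_per_run = NULL,
                        trials_per_block = 13,
                        block_duration_s = 60,
                        rest_duration_s = NULL,
                        initial_fixation_s = 3,
                        cue_duration_s = 2,
                        final_fixation_s = NULL,
                        stim_duration_s = 0.5,
                        iti_range_s = c(1.5, 10),
                        n_repeats_range = c(2, 4),
                        n_stimuli = 120,
                        seed = 1L) {
  variant <- match.arg(variant)
  if (variant == "long") {
    if (is.null(n_runs)) n_runs <- 4
    if (is.null(blocks_per_run)) blocks_per_run <- 3
    if (is.null(rest_duration_s)) rest_duration_s <- 30
    if (is.null(final_fixation_s)) final_fixation_s <- 10
  } else {
    if (is.null(n_runs)) n_runs <- 6
    if (is.null(blocks_per_run)) blocks_per_run <- 2
    if (is.null(rest_duration_s)) rest_duration_s <- 25
    if (is.null(final_fixation_s)) final_fixation_s <- 7
  }
  cfg <- list(
    variant = variant, n_runs = as.integer(n_runs),
    blocks_per_run = as.integer(blocks_per_run),
    trials_per_block = as.integer(trials_per_block),
    block_duration_s = block_duration_s,
    rest_duration_s = rest_duration_s,
    initial_fixation_s = initial_fixation_s,
    cue_duration_s = cue_duration_s,
    final_fixation_s = final_fixation_s,
    stim_duration_s = stim_duration_s,
    iti_range_s = iti_range_s,
    n_repeats_range = as.integer(n_repeats_range),
    n_stimuli = as.integer(n_stimuli),
    seed = as.integer(seed)
  )
  validate_task_config(cfg)
  class(cfg) <- "task_config"
  cfg
}

validate_task_config <- function(cfg) {
  if (cfg$n_runs < 0) stopf("invalid task config: n_runs must be >= 0")
  for (f in c("blocks_per_run", "trials_per_block")) {
    if (cfg[[f]] < 1) stopf("invalid task config: %s must be >= 1", f)
  }
  for (f in c("block_duration_s", "rest_duration_s", "cue_duration_s",
              "stim_duration_s")) {
    if (cfg[[f]] <= 0) stopf("invalid task config: %s must be > 0", f)
  }
  for (f in c("initial_fixation_s", "final_fixation_s")) {
    if (cfg[[f]] < 0) stopf("invalid task config: %s must be >= 0", f)
  }
  if (length(cfg$iti_range_s) != 2 || cfg$iti_range_s[1] >= cfg$iti_range_s[2]) {
    stopf("invalid task config: iti_range_s must be an increasing pair")
  }
  if (cfg$iti_range_s[1] <= 0) stopf("invalid task config: iti_range_s must be > 0")
  if (any(cfg$n_repeats_range < 1) || cfg$n_repeats_range[1] > cfg$n_repeats_range[2]) {
    stopf("invalid task config: n_repeats_range must be an increasing pair >= 1")
  }
  invisible(cfg)
}

#' Total run duration implied by the configured components
#'
#' `initial_fixation + B * block + (B - 1) * rest + final_fixation`
#' seconds; 155 s for the short variant. (The long variant's components
#' sum to 253 s.)
#'
#' @param config a [task_config()].
#' @return Run duration in seconds (scalar).
#' @export
run_duration <- function(config) {
  B <- config$blocks_per_run
  config$initial_fixation_s + B * config$block_duration_s +
    (B - 1) * config$rest_duration_s + config$final_fixation_s
}

# Jittered ITIs: drawn iid uniform on iti_range, then affinely rescaled
# above the 1.5-s floor so that cue + trials exactly fill the fixed
# block duration. Keeps every ITI inside the configured range.
draw_block_itis <- function(cfg) {
  k <- cfg$trials_per_block
  lo <- cfg$iti_range_s[1]
  hi <- cfg$iti_range_s[2]
  avail <- cfg$block_duration_s - cfg$cue_duration_s -
    k * cfg$stim_duration_s
  if (avail < k * lo) {
    stopf("invalid task config: block_duration_s too short for %d trials", k)
  }
  u <- stats::runif(k, lo, hi)
  gam <- (avail - k * lo) / sum(u - lo)
  iti <- lo + (u - lo) * gam
  # If blocks are roomy enough that rescaling would push ITIs above the
  # ceiling, clip and spread the excess over the remaining trials.
  while (any(iti > hi + 1e-9)) {
    over <- iti > hi
    excess <- sum(iti[over] - hi)
    iti[over] <- hi
    room <- which(!over)
    iti[room] <- iti[room] + excess / length(room)
  }
  iti
}

# Target positions: `n_rep` repeats per block, none before trial n+1
# (an n-back match needs n predecessors) and no two adjacent.
draw_target_positions <- function(k, n_rep, nback) {
  eligible <- seq.int(nback + 1L, k)
  repeat {
    pos <- sort(sample(eligible, n_rep))
    if (all(diff(pos) > 1L)) return(pos)
  }
}

#' Generate an n-back task schedule
#'
#' Lays out counterbalanced 1-back/2-back task blocks interleaved with
#' rest, a 2-s initiation cue per block, and jittered inter-trial
#' fixations drawn from the configured range. Conditions alternate
#' within each run and the starting condition alternates across runs,
#' so every session with an even total block count is exactly balanced.
#' Two to four target (repeat) trials are planted per block, never
#' adjacent. Onsets are placed on a 0.1-s grid.
#'
#' @param config a [task_config()].
#' @param session_label character session tag (e.g. `"baseline"`).
#' @return A `task_schedule`: a data.frame with columns `onset`
#'   (seconds from run start), `duration`, `condition` (`"1back"` /
#'   `"2back"`), `stimulus_id`, `is_target`, `accuracy` (initially
#'   `"unset"`), `run`, `block`; attributes `run_duration_s`,
#'   `session_label`, and `config`.
#' @export
generate_schedule <- function(config, session_label = "baseline") {
  validate_task_config(config)
  local_seed(config$seed, {
    rows <- vector("list", config$n_runs * config$blocks_per_run)
    idx <- 0L
    for (r in seq_len(config$n_runs)) {
      start_cond <- if (r %% 2L == 1L) 1L else 2L
      t_block <- config$initial_fixation_s
      for (b in seq_len(config$blocks_per_run)) {
        nback <- ((start_cond - 1L + b - 1L) %% 2L) + 1L
        cond <- paste0(nback, "back")
        k <- config$trials_per_block
        # ITIs snapped to the 0.1-s onset grid, range preserved
        iti <- pmin(pmax(round(draw_block_itis(config), 1),
                         config$iti_range_s[1]), config$iti_range_s[2])
        onsets <- t_block + config$cue_duration_s +
          c(0, cumsum(config$stim_duration_s + iti))[seq_len(k)]
        onsets <- round(onsets, 1)
        n_rep <- sample(seq.int(config$n_repeats_range[1],
                                config$n_repeats_range[2]), 1L)
        targets <- draw_target_positions(k, n_rep, nback)
        stim <- integer(k)
        for (j in seq_len(k)) {
          if (j %in% targets) {
            stim[j] <- stim[j - nback]
          } else {
            repeat {
              s <- sample.int(config$n_stimuli, 1L)
              if (j <= nback || s != stim[j - nback]) break
            }
            stim[j] <- s
          }
        }
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          onset = onsets,
          duration = config$stim_duration_s,
          condition = cond,
          stimulus_id = stim,
          is_target = seq_len(k) %in% targets,
          accuracy = "unset",
          run = r,
          block = b,
          stringsAsFactors = FALSE
        )
        t_block <- t_block + config$block_duration_s +
          if (b < config$blocks_per_run) config$rest_duration_s else 0
      }
    }
    trials <- if (idx > 0) do.call(rbind, rows[seq_len(idx)]) else
      data.frame(onset = numeric(), duration = numeric(),
                 condition = character(), stimulus_id = integer(),
                 is_target = logical(), accuracy = character(),
                 run = integer(), block = integer(),
                 stringsAsFactors = FALSE)
    new_task_schedule(trials,
                      run_duration_s = rep(run_duration(config),
                                           config$n_runs),
                      session_label = session_label,
                      config = config)
  })
}

new_task_schedule <- function(trials, run_duration_s, session_label,
                              config = NULL, extra = NULL) {
  structure(trials,
            run_duration_s = run_duration_s,
            session_label = session_label,
            config = config,
            extra_columns = extra,
            class = c("task_schedule", "data.frame"))
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("n-back task schedule (%s): %d trials, %d run(s)\n",
              attr(x, "session_label"), nrow(x),
              length(attr(x, "run_duration_s"))))
  if (nrow(x)) {
    tab <- table(x$condition)
    cat("  trials per condition:",
        paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  cat(sprintf("  run duration: %s s\n",
              paste(unique(attr(x, "run_duration_s")), collapse = ", ")))
  invisible(x)
}

#' Assign behavioral accuracy labels to a schedule
#'
#' Labels each trial `"correct"` with probability `accuracy_rate`
#' (independently), `"incorrect"` otherwise.
#'
#' @param schedule a `task_schedule`.
#' @param accuracy_rate probability in `[0, 1]`.
#' @param seed integer seed.
#' @return The schedule with its `accuracy` column filled in.
#' @export
label_accuracy <- function(schedule, accuracy_rate, seed = 1L) {
  if (!is.numeric(accuracy_rate) || accuracy_rate < 0 || accuracy_rate > 1) {
    stopf("accuracy_rate must lie in [0, 1]")
  }
  local_seed(seed, {
    ok <- stats::runif(nrow(schedule)) < accuracy_rate
    # boundary rates must be exact, not almost-sure
    if (accuracy_rate == 1) ok <- rep(TRUE, nrow(schedule))
    if (accuracy_rate == 0) ok <- rep(FALSE, nrow(schedule))
    schedule$accuracy <- ifelse(ok, "correct", "incorrect")
    schedule
  })
}

EVENTS_COLUMNS <- c("onset", "duration", "trial_type", "stimulus_id",
                    "is_target", "accuracy", "run", "block")

#' Write a schedule as a BIDS-style events table
#'
#' Tab-separated with header columns `onset`, `duration`, `trial_type`,
#' `stimulus_id`, `is_target`, `accuracy`, `run`, `block`. Onsets are
#' seconds from run start. A commented header line carries the session
#' label and per-run durations so [read_events()] can round-trip them.
#'
#' @param schedule a `task_schedule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# session=%s run_duration_s=%s",
                     attr(schedule, "session_label"),
                     paste(format(attr(schedule, "run_duration_s")),
                           collapse = ",")), con)
  df <- data.frame(
    onset = sprintf("%.1f", schedule$onset),
    duration = sprintf("%.1f", schedule$duration),
    trial_type = schedule$condition,
    stimulus_id = schedule$stimulus_id,
    is_target = ifelse(schedule$is_target, "1", "0"),
    accuracy = schedule$accuracy,
    run = schedule$run,
    block = schedule$block,
    stringsAsFactors = FALSE
  )
  writeLines(paste(EVENTS_COLUMNS, collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read an events table back into a schedule
#'
#' Parses a tab-separated events file written by [write_events()] (or any
#' BIDS-style events table with the required columns). Unknown columns
#' are preserved in the `extra_columns` attribute. Malformed rows are
#' reported with their row number.
#'
#' @param path events file path.
#' @return A `task_schedule`.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  session_label <- "unknown"
  run_duration_s <- numeric()
  header_meta <- grepl("^#", lines)
  for (ln in lines[header_meta]) {
    m <- regmatches(ln, regexec("session=(\\S+)", ln))[[1]]
    if (length(m) == 2) session_label <- m[2]
    m <- regmatches(ln, regexec("run_duration_s=(\\S+)", ln))[[1]]
    if (length(m) == 2) run_duration_s <- as.numeric(strsplit(m[2], ",")[[1]])
  }
  body <- lines[!header_meta]
  if (!length(body)) stopf("events file %s has no header row", path)
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- EVENTS_COLUMNS
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stopf("events file %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  for (col in c("onset", "duration")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stopf("events file %s: non-numeric %s at data row %d",
            path, col, bad[1])
    }
    tab[[col]] <- v
  }
  neg <- which(tab$onset < 0)
  if (length(neg)) {
    stopf("events file %s: negative onset at data row %d", path, neg[1])
  }
  extras <- setdiff(names(tab), required)
  trials <- data.frame(
    onset = tab$onset,
    duration = tab$duration,
    condition = as.character(tab$trial_type),
    stimulus_id = as.integer(tab$stimulus_id),
    is_target = as.integer(tab$is_target) != 0,
    accuracy = as.character(tab$accuracy),
    run = as.integer(tab$run),
    block = as.integer(tab$block),
    stringsAsFactors = FALSE
  )
  for (r in unique(trials$run)) {
    o <- trials$onset[trials$run == r]
    if (any(diff(o) <= 0)) {
      stopf("events file %s: onsets not strictly increasing in run %d",
            path, r)
    }
  }
  new_task_schedule(trials, run_duration_s = run_duration_s,
                    session_label = session_label,
                    extra = if (length(extras)) tab[extras] else NULL)
}
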