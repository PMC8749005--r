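#' Build a trial-wise GLM design matrix
#'
#' Each trial contributes three regressors — stimulus onset stick
#' convolved with the canonical HRF, its delay derivative, and its
#' dispersion derivative — computed on the basis' fine grid (0.1 s by
#' default, keeping jittered onsets exact) and resampled at the scanner
#' TR. Runs are stacked block-diagonally in time and each run gets an
#' intercept column.
#'
#' @param schedule a `task_schedule`.
#' @param basis an [hrf_basis()].
#' @param n_scans scans per run (scalar or one value per run).
#' @param TR repetition time, seconds (default 1).
#' @return A `design_matrix`: list with `X` (scans x columns), `trials`
#'   (the schedule rows in design order), `trial_columns` (index of each
#'   trial's 3 columns), `n_scans`, `TR`.
#' @export
build_design_matrix <- function(schedule, basis, n_scans, TR = 1) {
  runs <- sort(unique(schedule$run))
  if (length(n_scans) == 1) n_scans <- rep(n_scans, length(runs))
  if (length(n_scans) != length(runs)) {
    stopf("n_scans must be scalar or one value per run (%d runs)",
          length(runs))
  }
  late <- schedule$onset >= n_scans[match(schedule$run, runs)] * TR
  if (any(late)) {
    stopf("event(s) beyond scan end: trial row(s) %s",
          paste(which(late), collapse = ", "))
  }
  B <- basis_matrix(basis)
  n_trials <- nrow(schedule)
  total_scans <- sum(n_scans)
  X <- matrix(0, total_scans, 3L * n_trials + length(runs))
  cn <- character(ncol(X))
  trial_cols <- matrix(0L, n_trials, 3)
  row_off <- 0L
  dt <- basis$dt
  for (ri in seq_along(runs)) {
    ns <- n_scans[ri]
    n_fine <- ceiling(ns * TR / dt) + nrow(B)
    in_run <- which(schedule$run == runs[ri])
    scan_idx <- round(seq(0, by = TR, length.out = ns) / dt) + 1L
    for (j in in_run) {
      onset_idx <- round(schedule$onset[j] / dt) + 1L
      span <- onset_idx:min(onset_idx + nrow(B) - 1L, n_fine)
      cols <- (3L * (j - 1L) + 1L):(3L * j)
      fine <- matrix(0, n_fine, 3)
      fine[span, ] <- B[seq_along(span), ]
      X[row_off + seq_len(ns), cols] <- fine[scan_idx, ]
      trial_cols[j, ] <- cols
      cn[cols] <- paste0("trial", j, "_", c("can", "delay", "disp"))
    }
    icol <- 3L * n_trials + ri
    X[row_off + seq_len(ns), icol] <- 1
    cn[icol] <- paste0("run", runs[ri], "_intercept")
    row_off <- row_off + ns
  }
  colnames(X) <- cn
  zero <- which(colSums(abs(X)) == 0)
  if (length(zero)) {
    stopf("design has all-zero column(s): %s",
          paste(cn[zero], collapse = ", "))
  }
  # factor once; every participant fit against this design reuses it
  qrX <- qr(X)
  structure(list(X = X, trials = schedule, trial_columns = trial_cols,
                 n_scans = n_scans, TR = TR, basis = basis, qr = qrX,
                 kappa = kappa(qr.R(qrX), exact = FALSE)),
            class = "design_matrix")
}

#' Estimate trial-locked responses by beta-series GLM
#'
#' Ordinary least squares of every region's time course on the trial-wise
#' informed-basis design; each trial's evoked response is its three
#' fitted coefficients applied to the basis functions, evaluated on
#' `[0, window_s)` at TR resolution. Trials are ordered by condition,
#' accuracy, then onset. If the joint design is ill-conditioned
#' (condition number > 1e6, e.g. from very short ITIs), estimation falls
#' back to least-squares-separate: one GLM per trial with all remaining
#' trials collapsed into a single canonical regressor.
#'
#' @param ts regions x time numeric matrix (one session, runs
#'   concatenated in time).
#' @param design a [build_design_matrix()] result.
#' @param window_s response window, seconds (default 9).
#' @return A `response_matrix`: list with `values`
#'   (`n_trials * window` rows x regions), `labels` (data.frame: trial,
#'   condition, accuracy, run, sample, session, participant), `TR`,
#'   `window_s`.
#' @export
fit_trial_responses <- function(ts, design, window_s = 9,
                                session = "baseline", participant = 1L) {
  X <- design$X
  if (ncol(ts) != nrow(X)) {
    stopf("time series has %d scans but design expects %d",
          ncol(ts), nrow(X))
  }
  Y <- t(ts)
  qrX <- design$qr
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  n_trials <- nrow(design$trials)
  if (design$kappa <= 1e6) {
    beta <- qr.coef(qrX, Y)
  } else {
    beta <- fit_lss(X, Y, design)
  }
  Bw <- sample_basis_window(design$basis, window_s, design$TR)
  spt <- nrow(Bw)
  ord <- order(design$trials$condition, design$trials$accuracy,
               design$trials$run, design$trials$onset)
  values <- matrix(0, n_trials * spt, nrow(ts))
  labels <- vector("list", n_trials)
  for (i in seq_along(ord)) {
    j <- ord[i]
    bj <- beta[design$trial_columns[j, ], , drop = FALSE]
    values[(i - 1L) * spt + seq_len(spt), ] <- Bw %*% bj
    labels[[i]] <- data.frame(
      trial = j,
      condition = design$trials$condition[j],
      accuracy = design$trials$accuracy[j],
      run = design$trials$run[j],
      sample = seq_len(spt) - 1L,
      stringsAsFactors = FALSE
    )
  }
  labels <- do.call(rbind, labels)
  labels$session <- session
  labels$participant <- participant
  rn <- rownames(ts)
  colnames(values) <- if (is.null(rn)) paste0("region", seq_len(nrow(ts))) else rn
  new_response_matrix(values, labels, TR = design$TR, window_s = window_s)
}

# Least-squares-separate fallback for ill-conditioned joint designs.
fit_lss <- function(X, Y, design) {
  n_trials <- nrow(design$trials)
  beta <- matrix(0, ncol(X), ncol(Y))
  icols <- (3L * n_trials + 1L):ncol(X)
  can_cols <- design$trial_columns[, 1]
  for (j in seq_len(n_trials)) {
    own <- design$trial_columns[j, ]
    others <- rowSums(X[, setdiff(can_cols, own[1]), drop = FALSE])
    Xj <- cbind(X[, own, drop = FALSE], others, X[, icols, drop = FALSE])
    bj <- qr.coef(qr(Xj), Y)
    beta[own, ] <- bj[1:3, , drop = FALSE]
  }
  beta
}

new_response_matrix <- function(values, labels, TR, window_s) {
  stopifnot(nrow(values) == nrow(labels), all(is.finite(values)))
  structure(list(values = values, labels = labels, TR = TR,
                 window_s = window_s),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response matrix: %d samples x %d regions (TR = %g s, %g-s window)\n",
              nrow(x$values), ncol(x$values), x$TR, x$window_s))
  tab <- table(x$labels$condition, x$labels$accuracy)
  print(tab / (x$window_s / x$TR))
  invisible(x)
}

#' Concatenate response matrices
#'
#' Row-wise concatenation preserving sample labels. `mode = "per_session"`
#' requires all inputs to share a session label; `mode = "shared"`
#' concatenates across sessions to build a common embedding space.
#'
#' @param responses list of `response_matrix` objects.
#' @param mode `"per_session"` or `"shared"`.
#' @return A `response_matrix`.
#' @export
concatenate_responses <- function(responses, mode = c("per_session", "shared")) {
  mode <- match.arg(mode)
  stopifnot(length(responses) >= 1)
  ref <- responses[[1]]
  for (r in responses[-1]) {
    if (ncol(r$values) != ncol(ref$values) ||
        !identical(colnames(r$values), colnames(ref$values))) {
      stopf("region sets differ across response matrices")
    }
    if (r$TR != ref$TR) stopf("TR differs across response matrices")
  }
  if (mode == "per_session") {
    sess <- unique(unlist(lapply(responses, function(r) r$labels$session)))
    if (length(sess) > 1) {
      stopf("per_session concatenation given multiple sessions: %s",
            paste(sess, collapse = ", "))
    }
  }
  new_response_matrix(
    do.call(rbind, lapply(responses, `[[`, "values")),
    do.call(rbind, lapply(responses, `[[`, "labels")),
    TR = ref$TR, window_s = ref$window_s
  )
}

#' Group-average response matrix
#'
#' Averages participants' response matrices sample-by-sample, aligning
#' trials by their rank within each condition x accuracy cell. All
#' inputs must share the cell structure (equal per-cell trial counts),
#' which holds by construction when the cohort shares one schedule.
#'
#' @param responses list of `response_matrix` objects (one per
#'   participant).
#' @return A `response_matrix` with `participant = "group"`.
#' @export
group_mean_responses <- function(responses) {
  ref <- responses[[1]]
  key <- function(r) paste(r$labels$condition, r$labels$accuracy,
                           r$labels$sample, ave(seq_len(nrow(r$labels)),
                             paste(r$labels$condition, r$labels$accuracy,
                                   r$labels$sample), FUN = seq_along))
  k0 <- key(ref)
  acc <- ref$values
  for (r in responses[-1]) {
    if (!identical(key(r), k0)) {
      stopf("participants' cell structures differ; cannot align trials")
    }
    acc <- acc + r$values
  }
  labels <- ref$labels
  labels$participant <- "group"
  new_response_matrix(acc / length(responses), labels,
                      TR = ref$TR, window_s = ref$window_s)
}

#' Extract one condition x accuracy cell of a response matrix
#'
#' @param responses a `response_matrix`.
#' @param condition condition label (e.g. `"2back"`), or `NULL` for all.
#' @param accuracy accuracy label, or `NULL` for all.
#' @return A `response_matrix` restricted to the matching rows.
#' @export
response_cell <- function(responses, condition = NULL, accuracy = NULL) {
  keep <- rep(TRUE, nrow(responses$labels))
  if (!is.null(condition)) keep <- keep & responses$labels$condition %in% condition
  if (!is.null(accuracy)) keep <- keep & responses$labels$accuracy %in% accuracy
  if (!any(keep)) stopf("no samples match the requested cell")
  new_response_matrix(responses$values[keep, , drop = FALSE],
                      responses$labels[keep, , drop = FALSE],
                      TR = responses$TR, window_s = responses$window_s)
}
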