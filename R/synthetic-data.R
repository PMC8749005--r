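#' Ground-truth parameters for the BOLD simulator
#'
#' Defines the planted latent geometry: a smooth zero-centroid closed
#' curve in `latent_dim`-dimensional state space sampled at per-trial
#' anchor points. The 2-back trajectory is the 1-back curve rotated to a
#' different orientation and radially scaled by `expansion_factor` about
#' the origin, so latent arc length is exactly linear in the factor.
#' Incorrect trials are shrunk radially by `accuracy_shrink`. Region
#' signals are the latent courses mixed through a full-column-rank
#' loading matrix, convolved with the canonical HRF, plus AR(1) noise.
#'
#' @param n_regions number of parcels (default 333).
#' @param latent_dim latent dimensionality (default 3).
#' @param expansion_factor planted 2-back / 1-back length ratio (> 0).
#' @param accuracy_shrink radial factor for incorrect trials (default 0.4).
#' @param noise_sd marginal sd of the AR(1) region noise; `NULL` to set
#'   it from `target_snr` at simulation time.
#' @param target_snr trial-level signal-to-noise ratio (RMS clean
#'   single-trial response estimate / RMS estimation error; see
#'   [calibrate_noise_sd()]) used when `noise_sd` is `NULL` (default 2).
#' @param snr_reference whether `target_snr` describes the `"group"`
#'   mean series of the simulated cohort (the noise floor of the point
#'   cloud a group-level embedding sees, emulating a
#'   concatenated-participants embedding; the default) or each
#'   `"participant"` series individually.
#' @param ar1_coef AR(1) coefficient of the noise, `|phi| < 1`
#'   (default 0.4).
#' @param gain_sd sd of the per-participant amplitude gain around 1
#'   (default 0.1).
#' @param seed integer seed for the loading matrix.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(n_regions = 333, latent_dim = 3,
                         expansion_factor = 1.3, accuracy_shrink = 0.4,
                         noise_sd = NULL, target_snr = 2,
                         snr_reference = c("group", "participant"),
                         ar1_coef = 0.4, gain_sd = 0.1, seed = 1L) {
  snr_reference <- match.arg(snr_reference)
  if (expansion_factor <= 0) stopf("expansion_factor must be > 0")
  if (abs(ar1_coef) >= 1) stopf("ar1_coef must satisfy |phi| < 1")
  if (!is.null(noise_sd) && noise_sd < 0) stopf("noise_sd must be >= 0")
  if (accuracy_shrink <= 0) stopf("accuracy_shrink must be > 0")
  if (n_regions < latent_dim) stopf("need n_regions >= latent_dim")
  local_seed(seed, {
    # random loading matrix with orthonormal columns (full column rank)
    W <- qr.Q(qr(matrix(stats::rnorm(n_regions * latent_dim),
                        n_regions, latent_dim)))
    structure(list(n_regions = n_regions, latent_dim = latent_dim,
                   expansion_factor = expansion_factor,
                   accuracy_shrink = accuracy_shrink,
                   noise_sd = noise_sd, target_snr = target_snr,
                   snr_reference = snr_reference,
                   ar1_coef = ar1_coef, gain_sd = gain_sd,
                   loading_matrix = W, seed = seed),
              class = "ground_truth")
  })
}

# Zero-centroid closed 3-D loop evaluated at phases theta in [0, 2*pi).
base_loop <- function(theta) {
  pts <- cbind(cos(theta), sin(theta), 0.5 * sin(2 * theta))
  sweep(pts, 2, colMeans(pts))
}

# Per-trial latent anchors for one condition: loop points scaled by the
# planted geometry. The 2-back loop is a concentric radial expansion of
# the 1-back loop (load expands activity along the same latent modes);
# its anchors sit at half-step phase offsets so the two conditions never
# coincide exactly.
latent_anchors <- function(truth, condition, n_trials_condition) {
  theta <- 2 * pi * (seq_len(n_trials_condition) - 1) / n_trials_condition
  if (condition == "2back") theta <- theta + pi / n_trials_condition
  pts <- base_loop(theta)
  if (truth$latent_dim > 3) {
    pts <- cbind(pts, matrix(0, nrow(pts), truth$latent_dim - 3))
  } else if (truth$latent_dim < 3) {
    pts <- pts[, seq_len(truth$latent_dim), drop = FALSE]
  }
  if (condition == "2back") {
    pts <- truth$expansion_factor * pts
  }
  pts
}

# Analytic arc length of the (closed) polygon through the anchors.
polygon_length <- function(pts) {
  d <- diff(rbind(pts, pts[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Simulate one parcellated BOLD session
#'
#' Places each trial's latent anchor as a 1-s neural epoch at its onset,
#' scaled by condition expansion, accuracy shrink, and the participant
#' gain; convolves the latent courses with the canonical HRF on the fine
#' grid; mixes into regions through the loading matrix; and adds AR(1)
#' Gaussian noise. Ground truth (anchors, analytic lengths, convolved
#' latent courses) is returned alongside.
#'
#' @param config a [task_config()].
#' @param truth a [ground_truth()].
#' @param seed integer seed for the noise (and accuracy labels).
#' @param schedule optionally, a pre-built labelled `task_schedule`
#'   (lets a cohort share one schedule).
#' @param accuracy_rate probability a trial is correct (default 1).
#' @param gain participant amplitude gain (default 1).
#' @param session_label session tag.
#' @param participant participant id.
#' @return A `simulated_session`: list with `ts` (regions x time), the
#'   labelled `schedule`, `truth`, `latent_tr` (convolved latent courses
#'   at TR), `clean` (noiseless regions x time), `noise_sd_used`,
#'   `anchors` (per-trial latent anchors in schedule row order), and
#'   analytic `latent_lengths` per cell.
# Deterministic part of a session: per-trial anchors and the
# HRF-convolved latent courses sampled at TR.
simulate_clean <- function(schedule, truth, TR = 1, dt = 0.1,
                           epoch_s = 1) {
  run_dur <- attr(schedule, "run_duration_s")
  n_scans <- as.integer(round(run_dur / TR))
  basis <- hrf_basis(dt = dt)
  h <- basis$canonical

  # per-trial anchors (phase = trial rank within its condition)
  anchors <- matrix(0, nrow(schedule), truth$latent_dim)
  for (cond in unique(schedule$condition)) {
    rows <- which(schedule$condition == cond)
    pts <- latent_anchors(truth, cond, length(rows))
    shrink <- ifelse(schedule$accuracy[rows] == "incorrect",
                     truth$accuracy_shrink, 1)
    anchors[rows, ] <- pts * shrink
  }

  latent_tr <- NULL
  for (r in seq_along(run_dur)) {
    nf <- as.integer(round(run_dur[r] / dt))
    L <- matrix(0, nf, truth$latent_dim)
    rows <- which(schedule$run == r)
    for (j in rows) {
      i0 <- as.integer(round(schedule$onset[j] / dt)) + 1L
      i1 <- min(i0 + as.integer(epoch_s / dt) - 1L, nf)
      L[i0:i1, ] <- L[i0:i1, ] +
        matrix(anchors[j, ], i1 - i0 + 1L, truth$latent_dim, byrow = TRUE)
    }
    Lc <- apply(L, 2, function(col) {
      conv <- stats::convolve(col, rev(h), type = "open")[seq_len(nf)]
      conv * dt
    })
    idx <- as.integer(round(seq(0, by = TR, length.out = n_scans[r]) / dt)) + 1L
    latent_tr <- rbind(latent_tr, Lc[idx, , drop = FALSE])
  }
  list(latent_tr = latent_tr, anchors = anchors, n_scans = n_scans)
}

# AR(1) noise matrix (scans x k) with unit marginal sd; stats::filter
# handles all columns in one call.
ar1_noise <- function(n, k, phi) {
  e <- matrix(stats::rnorm(n * k), n, k)
  if (phi != 0) {
    e <- unclass(stats::filter(e, phi, method = "recursive")) *
      sqrt(1 - phi^2)
    dim(e) <- c(n, k)
  }
  e
}

#' Calibrate noise to a target trial-level SNR
#'
#' Trial-level SNR is defined on the pipeline's own estimates: the RMS
#' amplitude of the noiseless estimated single-trial responses divided
#' by the RMS of the estimation error in those responses for one
#' participant. Both terms are measured empirically by fitting the
#' trial-wise GLM to (a) the clean signal and (b) unit-variance AR(1)
#' probe series, so the calibration automatically accounts for the
#' design's conditioning and the noise autocorrelation.
#'
#' @param schedule a labelled `task_schedule`.
#' @param truth a [ground_truth()].
#' @param target_snr desired trial-level SNR.
#' @param n_probe number of unit-noise probe series (default 8).
#' @param seed seed for the probes.
#' @return Calibrated `noise_sd` (scalar).
#' @export
calibrate_noise_sd <- function(schedule, truth, target_snr = 2,
                               n_probe = 8, seed = 1L) {
  clean <- simulate_clean(schedule, truth)
  basis <- hrf_basis()
  design <- build_design_matrix(schedule, basis, n_scans = clean$n_scans)
  # clean trial responses at the latent level, mapped through the
  # (orthonormal-column) loading matrix: RMS over regions equals RMS
  # over latent dims scaled by sqrt(latent_dim / n_regions)
  fit_c <- fit_trial_responses(t(clean$latent_tr), design)
  c_rms <- sqrt(mean(fit_c$values^2) * truth$latent_dim / truth$n_regions)
  probes <- local_seed(seed, {
    ar1_noise(sum(clean$n_scans), n_probe, truth$ar1_coef)
  })
  fit_e <- fit_trial_responses(t(probes), design)
  e_rms <- sqrt(mean(fit_e$values^2))
  c_rms / (target_snr * e_rms)
}

#' @export
simulate_session <- function(config, truth, seed = 1L,
                             schedule = NULL, accuracy_rate = 1,
                             gain = 1, session_label = "baseline",
                             participant = 1L) {
  TR <- 1
  if (is.null(schedule)) {
    schedule <- generate_schedule(config, session_label = session_label)
    schedule <- label_accuracy(schedule, accuracy_rate, seed = seed + 1L)
  }
  cl <- simulate_clean(schedule, truth, TR = TR)
  latent_tr <- cl$latent_tr
  anchors <- cl$anchors
  n_scans <- cl$n_scans
  clean <- gain * (latent_tr %*% t(truth$loading_matrix))

  noise_sd <- truth$noise_sd
  if (is.null(noise_sd)) {
    noise_sd <- calibrate_noise_sd(schedule, truth,
                                   target_snr = truth$target_snr,
                                   seed = seed + 3L)
  }
  ts <- local_seed(seed, {
    noise <- ar1_noise(nrow(clean), ncol(clean), truth$ar1_coef)
    t(clean + noise_sd * noise)
  })
  rownames(ts) <- paste0("region", seq_len(truth$n_regions))

  cells <- unique(schedule[c("condition", "accuracy")])
  latent_lengths <- apply(cells, 1, function(cl) {
    rows <- schedule$condition == cl[["condition"]] &
      schedule$accuracy == cl[["accuracy"]]
    gain * polygon_length(anchors[rows, , drop = FALSE])
  })
  names(latent_lengths) <- paste(cells$condition, cells$accuracy, sep = ".")

  structure(list(ts = ts, schedule = schedule, truth = truth,
                 latent_tr = latent_tr, clean = t(clean),
                 noise_sd_used = noise_sd, anchors = anchors,
                 latent_lengths = latent_lengths,
                 TR = TR, n_scans = n_scans,
                 session_label = session_label,
                 participant = participant),
            class = "simulated_session")
}

#' Simulate a cohort of participants for one session
#'
#' All participants share the schedule, latent curve, and loading matrix
#' (a fixed stimulus sequence presented to everyone); they differ in
#' AR(1) noise realizations and in a per-participant amplitude gain
#' `~ N(1, gain_sd)`. Optionally plants a linear association between
#' participants' gains (hence trajectory lengths) and a behavioral
#' accuracy score.
#'
#' @param n_participants cohort size (default 17).
#' @param config a [task_config()].
#' @param truth a [ground_truth()].
#' @param seed integer master seed.
#' @param accuracy_rate trial-level probability correct (default 1).
#' @param behavior_cor planted correlation between gain and the returned
#'   behavioral score (default 0.5; `NA` for no behavior table).
#' @param session_label session tag.
#' @return A `simulated_cohort`: list of `simulated_session`s plus the
#'   shared `schedule`, `truth`, `gains`, and a `behavior` data.frame.
#' @export
simulate_cohort <- function(n_participants = 17, config, truth,
                            seed = 1L, accuracy_rate = 1,
                            behavior_cor = 0.5,
                            session_label = "baseline") {
  schedule <- local_seed(seed, {
    s <- generate_schedule(config, session_label = session_label)
    label_accuracy(s, accuracy_rate, seed = seed + 7L)
  })
  gains <- local_seed(seed + 11L, {
    pmax(stats::rnorm(n_participants, 1, truth$gain_sd), 0.2)
  })
  if (is.null(truth$noise_sd)) {
    # calibrate once at unit gain; all participants share the noise
    # scale. Under the "group" reference the per-participant noise is
    # sqrt(n) larger so the n-participant mean series sits at target_snr.
    truth$noise_sd <- calibrate_noise_sd(schedule, truth,
                                         target_snr = truth$target_snr,
                                         seed = seed + 3L)
    if (truth$snr_reference == "group") {
      truth$noise_sd <- truth$noise_sd * sqrt(n_participants)
    }
  }
  sessions <- lapply(seq_len(n_participants), function(p) {
    simulate_session(config, truth, seed = seed + 100L * p,
                     schedule = schedule, gain = gains[p],
                     session_label = session_label, participant = p)
  })
  behavior <- NULL
  if (!is.na(behavior_cor)) {
    behavior <- local_seed(seed + 13L, {
      z <- scale(gains)[, 1]
      e <- stats::rnorm(n_participants)
      score <- behavior_cor * z +
        sqrt(max(0, 1 - behavior_cor^2)) * scale(e)[, 1]
      data.frame(participant = seq_len(n_participants),
                 gain = gains,
                 accuracy_2back = 0.8 + 0.1 * score)
    })
  }
  structure(list(sessions = sessions, schedule = schedule, truth = truth,
                 gains = gains, behavior = behavior,
                 session_label = session_label),
            class = "simulated_cohort")
}

#' Toy manifolds for embedding tests
#'
#' @param kind `"noisy_curve"` (points along a smooth 1-D curve with a
#'   known ordering), `"gaussian_blobs"` (isotropic clusters with known
#'   labels), or `"two_clusters"` (two tight clusters whose gap is at
#'   least 10x their internal spread).
#' @param n_points number of points (>= 10).
#' @param ambient_dim ambient dimensionality (>= 3).
#' @param noise_sd additive isotropic noise sd.
#' @param seed integer seed.
#' @param n_blobs number of blobs for `"gaussian_blobs"` (default 3).
#' @return List with `X` (`n_points` x `ambient_dim`), plus
#'   `ordering`/`t` for curves, `labels`/`centers` for clusters.
#' @export
make_toy_manifold <- function(kind = c("noisy_curve", "gaussian_blobs",
                                       "two_clusters"),
                              n_points = 200, ambient_dim = 10,
                              noise_sd = 0.05, seed = 1L, n_blobs = 3) {
  kind <- match.arg(kind)
  if (n_points < 10) stopf("n_points must be >= 10")
  if (ambient_dim < 3) stopf("ambient_dim must be >= 3")
  local_seed(seed, {
    basis <- qr.Q(qr(matrix(stats::rnorm(ambient_dim * 3), ambient_dim, 3)))
    if (kind == "noisy_curve") {
      s <- seq(0, 1, length.out = n_points)
      curve3 <- cbind(cos(pi * s), sin(pi * s), s)
      X <- curve3 %*% t(basis) +
        noise_sd * matrix(stats::rnorm(n_points * ambient_dim),
                          n_points, ambient_dim)
      list(X = X, ordering = seq_len(n_points), t = s, kind = kind)
    } else if (kind == "gaussian_blobs") {
      centers3 <- matrix(stats::rnorm(n_blobs * 3, sd = 4), n_blobs, 3)
      labels <- rep(seq_len(n_blobs), length.out = n_points)
      X <- centers3[labels, , drop = FALSE] %*% t(basis) +
        noise_sd * matrix(stats::rnorm(n_points * ambient_dim),
                          n_points, ambient_dim)
      list(X = X, labels = labels,
           centers = centers3 %*% t(basis), kind = kind)
    } else {
      spread <- max(noise_sd, 1e-3)
      centers3 <- rbind(c(0, 0, 0), c(30 * spread, 0, 0))
      labels <- rep(1:2, length.out = n_points)
      X <- centers3[labels, , drop = FALSE] %*% t(basis) +
        spread * matrix(stats::rnorm(n_points * ambient_dim),
                        n_points, ambient_dim)
      list(X = X, labels = labels,
           centers = centers3 %*% t(basis), kind = kind)
    }
  })
}
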