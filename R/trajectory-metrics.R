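#' Construct a trajectory from embedded points
#'
#' A trajectory is the time-ordered path of embedded brain-activity
#' points for one condition x accuracy x session cell. All geometry
#' statistics operate on trajectories, and comparisons across different
#' embedding spaces are rejected.
#'
#' @param points ordered coordinate matrix (>= 2 rows).
#' @param condition,accuracy,session,participant cell labels.
#' @param embedding_id id of the embedding space the points came from.
#' @return A `trajectory` object.
#' @export
trajectory <- function(points, condition = NA, accuracy = NA,
                       session = NA, participant = NA,
                       embedding_id = "unspecified") {
  points <- as.matrix(points)
  if (nrow(points) < 2) stopf("a trajectory needs >= 2 points")
  if (!all(is.finite(points))) stopf("trajectory coordinates must be finite")
  structure(list(points = points, condition = condition,
                 accuracy = accuracy, session = session,
                 participant = participant, embedding_id = embedding_id),
            class = "trajectory")
}

#' Extract per-cell trajectories from an embedding
#'
#' Splits a labelled embedding into one trajectory per condition x
#' accuracy (x participant) cell, points ordered as embedded (trial
#' onset order within cell).
#'
#' @param embedding a `phate_embedding` with `labels`.
#' @param dims number of leading dimensions to keep (default 3).
#' @param by label columns defining cells
#'   (default `c("condition", "accuracy")`).
#' @return Named list of `trajectory` objects.
#' @export
extract_trajectories <- function(embedding, dims = 3,
                                 by = c("condition", "accuracy")) {
  lab <- embedding$labels
  if (is.null(lab)) stopf("embedding carries no sample labels")
  key <- interaction(lab[by], drop = TRUE, sep = ".")
  out <- lapply(levels(key), function(k) {
    rows <- which(key == k)
    cell <- lab[rows[1], , drop = FALSE]
    trajectory(embedding$coords[rows, seq_len(dims), drop = FALSE],
               condition = cell$condition, accuracy = cell$accuracy,
               session = cell$session,
               participant = cell$participant,
               embedding_id = embedding$embedding_id)
  })
  names(out) <- levels(key)
  out
}

#' Trajectory length
#'
#' Total summed Euclidean distance over consecutive points in the first
#' `dims` coordinates.
#'
#' @param traj a `trajectory` (or plain coordinate matrix).
#' @param dims leading dimensions used (default 3, capped at the
#'   trajectory's dimensionality).
#' @return Length (scalar).
#' @export
trajectory_length <- function(traj, dims = 3) {
  pts <- if (inherits(traj, "trajectory")) traj$points else as.matrix(traj)
  if (nrow(pts) < 2) stopf("a trajectory needs >= 2 points")
  dims <- min(dims, ncol(pts))
  pts <- pts[, seq_len(dims), drop = FALSE]
  steps <- diff(pts)
  sum(sqrt(rowSums(steps^2)))
}

# Linear index-resampling of a trajectory to n points.
resample_points <- function(pts, n) {
  m <- nrow(pts)
  if (m == n) return(pts)
  at <- seq(1, m, length.out = n)
  lo <- pmin(floor(at), m - 1L)
  w <- at - lo
  pts[lo, , drop = FALSE] * (1 - w) + pts[lo + 1L, , drop = FALSE] * w
}

check_same_space <- function(a, b) {
  if (!identical(a$embedding_id, b$embedding_id)) {
    stopf("trajectories come from different embedding spaces (%s vs %s)",
          a$embedding_id, b$embedding_id)
  }
}

#' Condition expansion ratio
#'
#' Ratio of trajectory lengths, e.g. 2-back over 1-back: the core
#' effect measure of load-induced state-space expansion. Both
#' trajectories must live in the same embedding space.
#'
#' @param numerator,denominator `trajectory` objects.
#' @param dims leading dimensions used (default 3).
#' @return Length ratio (scalar).
#' @export
expansion_ratio <- function(numerator, denominator, dims = 3) {
  check_same_space(numerator, denominator)
  den <- trajectory_length(denominator, dims)
  if (den == 0) stopf("denominator trajectory has zero length")
  trajectory_length(numerator, dims) / den
}

#' Total summed distance between group and individual trajectories
#'
#' `sum_i ||g_i - p_i||` over index-matched points in the first `dims`
#' coordinates. Point counts normally match by construction (same trial
#' grid); if they differ the individual trajectory is linearly resampled
#' to the group grid (with a message) unless `resample = FALSE`.
#'
#' @param group,individual `trajectory` objects in one embedding space.
#' @param dims leading dimensions used (default 3).
#' @param resample allow linear resampling on count mismatch
#'   (default TRUE).
#' @return Summed Euclidean distance (scalar).
#' @export
group_individual_distance <- function(group, individual, dims = 3,
                                      resample = TRUE) {
  check_same_space(group, individual)
  g <- group$points[, seq_len(min(dims, ncol(group$points))), drop = FALSE]
  p <- individual$points[, seq_len(ncol(g)), drop = FALSE]
  if (nrow(g) != nrow(p)) {
    if (!resample) {
      stopf("point counts differ (%d vs %d) and resampling is disabled",
            nrow(g), nrow(p))
    }
    message(sprintf("resampling individual trajectory %d -> %d points",
                    nrow(p), nrow(g)))
    p <- resample_points(p, nrow(g))
  }
  sum(sqrt(rowSums((g - p)^2)))
}

#' Load-induced scaling of trajectory distances
#'
#' Least-squares slope and Pearson correlation of participants' 2-back
#' group-individual distances on their 1-back distances: a positive
#' linear relationship indicates that individual deviations from the
#' group trajectory scale with working-memory load.
#'
#' @param distances_1back,distances_2back numeric vectors, one value per
#'   participant (equal lengths >= 3).
#' @return List with `slope`, `intercept`, `r`, `p`, `n`.
#' @export
load_scaling <- function(distances_1back, distances_2back) {
  n <- length(distances_1back)
  if (length(distances_2back) != n) stopf("participant counts differ")
  if (n < 3) stopf("need >= 3 participants")
  if (stats::sd(distances_1back) == 0) {
    stopf("zero variance in the 1-back distances")
  }
  fit <- stats::lm(distances_2back ~ distances_1back)
  ct <- stats::cor.test(distances_1back, distances_2back)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Trajectory length - behavior association
#'
#' Pearson correlation between participants' trajectory lengths and a
#' behavioral score (e.g. overall 2-back accuracy), with two-sided p.
#'
#' @param lengths,accuracy numeric vectors per participant (n >= 4).
#' @return List with `r`, `p`, `n`.
#' @export
behavior_association <- function(lengths, accuracy) {
  n <- length(lengths)
  if (length(accuracy) != n) stopf("input lengths differ")
  if (n < 4) stopf("need >= 4 participants")
  if (!all(is.finite(lengths)) || !all(is.finite(accuracy))) {
    stopf("inputs must be finite")
  }
  if (stats::sd(lengths) == 0 || stats::sd(accuracy) == 0) {
    stopf("constant input")
  }
  ct <- stats::cor.test(lengths, accuracy)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
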