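#' Alpha-decay affinity kernel with adaptive bandwidth
#'
#' Pairwise Euclidean distances between the rows of `X` (time samples
#' across region features) are turned into affinities
#' `K_ij = 1/2 exp(-(d_ij / eps_k(i))^alpha) + 1/2 exp(-(d_ij / eps_k(j))^alpha)`,
#' where `eps_k(i)` is the distance from point `i` to its `knn`-th
#' nearest neighbor. The kernel is symmetric by construction, has unit
#' diagonal, and with a large decay exponent (default 35) sharpens each
#' point's neighborhood to roughly its `knn` nearest points.
#'
#' @param X numeric matrix, points in rows.
#' @param knn neighbor index defining the adaptive bandwidth (default 10).
#' @param alpha decay exponent (default 35).
#' @return An `affinity_matrix`: list with `K`, `bandwidths`, `knn`,
#'   `alpha`.
#' @export
alpha_decay_kernel <- function(X, knn = 10, alpha = 35) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (knn < 1 || knn >= n) stopf("need 1 <= knn < n_points (n = %d)", n)
  if (alpha <= 0) stopf("alpha must be > 0")
  D <- row_dist(X)
  diag(D) <- 0
  # adaptive bandwidth: distance to the knn-th neighbor (self excluded)
  # self-distance 0 is the smallest order statistic, so the knn-th
  # neighbor is the (knn + 1)-th sorted value
  eps <- apply(D, 1, function(d) sort(d)[knn + 1L])
  if (any(eps == 0)) {
    stopf(paste("zero bandwidth at point(s) %s (>= knn duplicates);",
                "deduplicate or jitter the input"),
          paste(utils::head(which(eps == 0), 5), collapse = ", "))
  }
  A <- exp(-(D / eps)^alpha)          # rows scaled by eps_i
  K <- 0.5 * (A + t(A))
  diag(K) <- 1
  structure(list(K = K, bandwidths = eps, knn = knn, alpha = alpha),
            class = "affinity_matrix")
}

#' Row-stochastic diffusion operator
#'
#' Row-normalizes an affinity matrix into random-walk transition
#' probabilities and caches the eigendecomposition of the symmetric
#' conjugate `D^{1/2} P D^{-1/2}` (same spectrum as `P`), used for von
#' Neumann entropy and fast powering.
#'
#' @param affinity an [alpha_decay_kernel()] result, or a plain
#'   symmetric nonnegative matrix.
#' @return A `diffusion_operator`: list with `P`, `degrees`,
#'   `evalues`, `evectors` (of the symmetric conjugate), `K`.
#' @export
diffusion_operator <- function(affinity) {
  K <- if (inherits(affinity, "affinity_matrix")) affinity$K else as.matrix(affinity)
  if (any(K < 0)) stopf("affinities must be nonnegative")
  d <- rowSums(K)
  if (any(d == 0)) {
    stopf("zero row sum at point(s) %s",
          paste(utils::head(which(d == 0), 5), collapse = ", "))
  }
  P <- K / d
  s <- 1 / sqrt(d)
  S <- K * tcrossprod(s)             # D^{-1/2} K D^{-1/2}, symmetric
  eig <- eigen(S, symmetric = TRUE)
  structure(list(P = P, degrees = d, evalues = eig$values,
                 evectors = eig$vectors, K = K),
            class = "diffusion_operator")
}

#' Von Neumann entropy curve of a diffusion operator
#'
#' `H(t) = -sum eta_i log eta_i` with `eta_i = |lambda_i|^t / sum_j
#' |lambda_j|^t` over the operator's eigenvalues.
#'
#' @param op a [diffusion_operator()].
#' @param t_max largest diffusion time evaluated.
#' @return Numeric vector `H(1), ..., H(t_max)`.
#' @export
vne_curve <- function(op, t_max = 100) {
  lam <- abs(op$evalues)
  vapply(seq_len(t_max), function(t) {
    p <- lam^t
    p <- p / sum(p)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
}

#' Select the diffusion time at the entropy knee
#'
#' Evaluates the von Neumann entropy for `t = 1..t_max` and returns the
#' knee: the `t` with maximum perpendicular distance from the chord
#' joining `(1, H(1))` and `(t_max, H(t_max))`. The knee marks the
#' transition from fast noise-eigenvalue decay to the slow decay of
#' structure, i.e. the denoising scale of the random walk.
#'
#' @param op a [diffusion_operator()].
#' @param t_max search cap (default 100, must be >= 3).
#' @return Integer diffusion time, with the entropy curve attached as
#'   attribute `"vne"`.
#' @export
select_t_vne <- function(op, t_max = 100) {
  if (t_max < 3) stopf("t_max must be >= 3")
  H <- vne_curve(op, t_max)
  if (max(H) - min(H) < 1e-10) {
    stopf("entropy curve is constant: no knee; supply t explicitly")
  }
  tt <- seq_len(t_max)
  # perpendicular distance from the chord (1, H[1]) -- (t_max, H[t_max])
  v <- c(t_max - 1, H[t_max] - H[1])
  v <- v / sqrt(sum(v^2))
  dx <- tt - 1
  dy <- H - H[1]
  perp <- abs(dx * v[2] - dy * v[1])
  t_sel <- as.integer(which.max(perp))
  attr(t_sel, "vne") <- H
  t_sel
}

# P^t through the cached symmetric-conjugate eigendecomposition:
# P^t = D^{-1/2} V diag(lambda^t) V' D^{1/2}.
power_operator <- function(op, t) {
  s <- sqrt(op$degrees)
  V <- op$evectors
  Pt <- (V %*% (op$evalues^t * t(V)))
  Pt <- Pt * tcrossprod(1 / s, s)
  Pt[Pt < 0] <- 0
  Pt
}

#' Potential distances between diffusion profiles
#'
#' `U_ij = || log(P^t_i. + gamma) - log(P^t_j. + gamma) ||_2`: the
#' Euclidean distance between log-transformed t-step random-walk
#' profiles. Requires a connected affinity graph (otherwise `P^t`
#' entries vanish structurally and the log floors dominate); the
#' component structure is checked first.
#'
#' @param op a [diffusion_operator()].
#' @param t diffusion time (integer >= 1).
#' @param gamma log floor guarding against underflow (default 1e-12).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
potential_distance <- function(op, t, gamma = 1e-12) {
  comp <- graph_components(op$K > 0)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stopf("affinity graph has %d connected components (sizes %s)",
          max(comp), paste(sizes, collapse = ", "))
  }
  Pt <- power_operator(op, t)
  L <- log(Pt + gamma)
  U <- row_dist(L)
  U <- 0.5 * (U + t(U))
  diag(U) <- 0
  U
}

#' Metric MDS by stress majorization
#'
#' Initializes with classical (double-centering) MDS and refines by
#' SMACOF iterations minimizing the raw stress
#' `sum_{i<j} (U_ij - ||y_i - y_j||)^2`. Deterministic given its inputs;
#' stress never increases across iterations. Output dimensions are
#' ordered by decreasing variance.
#'
#' @param U symmetric distance matrix, zero diagonal.
#' @param n_dims embedding dimensionality (default 5).
#' @param max_iter maximum SMACOF iterations (default 50).
#' @param tol relative stress-decrease stopping tolerance (default 1e-6).
#' @return List with `coords` (n x n_dims), `stress` (final raw stress),
#'   `stress_initial`, `n_iter`, `variance_fraction`.
#' @export
metric_mds <- function(U, n_dims = 5, max_iter = 50, tol = 1e-6) {
  U <- as.matrix(U)
  n <- nrow(U)
  if (!isTRUE(all.equal(U, t(U), tolerance = 1e-8))) {
    stopf("distance matrix must be symmetric")
  }
  if (n_dims >= n) stopf("n_dims must be < n_points")
  # classical MDS initialization
  U2 <- U^2
  B <- -0.5 * (U2 - outer(rowMeans(U2), colMeans(U2), "+") + mean(U2))
  eig <- eigen(B, symmetric = TRUE)
  lam <- pmax(eig$values[seq_len(n_dims)], 0)
  X <- eig$vectors[, seq_len(n_dims), drop = FALSE] %*% diag(sqrt(lam), n_dims)

  stress_of <- function(D) sum((U - D)^2) / 2
  D <- row_dist(X)
  s0 <- stress_of(D)
  s_prev <- s0
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Dpos <- D
    Dpos[Dpos == 0] <- Inf                # Guttman transform, 0/0 -> 0
    Bmat <- -U / Dpos
    diag(Bmat) <- 0
    diag(Bmat) <- -rowSums(Bmat)
    X <- (Bmat %*% X) / n
    D <- row_dist(X)
    s_new <- stress_of(D)
    if (s_prev - s_new < tol * max(s_prev, .Machine$double.eps)) {
      s_prev <- min(s_prev, s_new)
      break
    }
    s_prev <- s_new
  }
  vf <- apply(X, 2, stats::var)
  ord <- order(vf, decreasing = TRUE)
  X <- X[, ord, drop = FALSE]
  colnames(X) <- paste0("dim", seq_len(n_dims))
  list(coords = X, stress = s_prev, stress_initial = s0, n_iter = iter,
       variance_fraction = variance_explained(X))
}

#' Per-dimension variance fractions of an embedding
#'
#' @param coords n x d coordinate matrix (d >= 2).
#' @return Fractions summing to 1 across the retained dimensions.
#' @export
variance_explained <- function(coords) {
  if (ncol(coords) < 2) stopf("need >= 2 retained dimensions")
  v <- apply(coords, 2, stats::var)
  tot <- sum(v)
  if (tot == 0) stopf("embedding has zero total variance")
  v / tot
}

#' Region weights on embedding dimensions
#'
#' The spatial weight of region `r` on dimension `d` is the Pearson
#' correlation between the region's concatenated response course and the
#' embedding coordinate course. This is a reconstruction: it projects
#' each embedding dimension back onto the parcellation as the simplest
#' definition of a region's engagement with that dimension.
#'
#' @param responses a `response_matrix` whose rows align 1:1 with
#'   `coords` rows.
#' @param coords embedding coordinates (n x d).
#' @return Regions x dimensions weight matrix; zero-variance regions get
#'   weight 0 with a warning.
#' @export
spatial_weights <- function(responses, coords) {
  V <- responses$values
  if (nrow(V) != nrow(coords)) {
    stopf("responses (%d rows) and coords (%d rows) must align 1:1",
          nrow(V), nrow(coords))
  }
  sds <- apply(V, 2, stats::sd)
  W <- matrix(0, ncol(V), ncol(coords),
              dimnames = list(colnames(V), colnames(coords)))
  ok <- sds > 0
  if (any(!ok)) {
    warning(sprintf("%d zero-variance region(s) given weight 0",
                    sum(!ok)), call. = FALSE)
  }
  W[ok, ] <- stats::cor(V[, ok, drop = FALSE], coords)
  W
}

#' Diffusion-potential manifold embedding
#'
#' The full embedding recipe: alpha-decay affinity kernel with adaptive
#' k-nearest-neighbor bandwidth, row-stochastic diffusion operator,
#' diffusion-time selection at the von Neumann entropy knee (unless `t`
#' is given), potential distances between t-step diffusion profiles, and
#' metric MDS by stress majorization.
#'
#' @param X numeric matrix (points x features) or a `response_matrix`.
#' @param n_dims embedding dimensions (default 5; trajectories use the
#'   top 3).
#' @param knn adaptive-bandwidth neighbor (default 10).
#' @param alpha kernel decay exponent (default 35).
#' @param t diffusion time: `"auto"` (entropy knee) or a positive
#'   integer (the study's group value is 32).
#' @param t_max entropy-knee search cap (default 100).
#' @param mds_max_iter,mds_tol majorization controls.
#' @param weights if `TRUE` and `X` is a `response_matrix`, attach
#'   region spatial weights.
#' @return A `phate_embedding`: list with `coords`,
#'   `variance_fraction`, `stress`, `t_selected`, `vne`, `params`,
#'   `labels` (when `X` carried sample labels), `spatial_weights`.
#' @export
phate_embed <- function(X, n_dims = 5, knn = 10, alpha = 35,
                        t = "auto", t_max = 100,
                        mds_max_iter = 50, mds_tol = 1e-6,
                        weights = TRUE) {
  labels <- NULL
  responses <- NULL
  if (inherits(X, "response_matrix")) {
    responses <- X
    labels <- X$labels
    X <- X$values
  }
  aff <- alpha_decay_kernel(X, knn = knn, alpha = alpha)
  op <- diffusion_operator(aff)
  vne <- NULL
  if (identical(t, "auto")) {
    t_sel <- select_t_vne(op, t_max = t_max)
    vne <- attr(t_sel, "vne")
    t_sel <- as.integer(t_sel)
  } else {
    t_sel <- as.integer(t)
    if (t_sel < 1) stopf("t must be a positive integer or \"auto\"")
  }
  U <- potential_distance(op, t_sel)
  mds <- metric_mds(U, n_dims = n_dims, max_iter = mds_max_iter,
                    tol = mds_tol)
  sw <- NULL
  if (weights && !is.null(responses)) {
    sw <- spatial_weights(responses, mds$coords)
  }
  structure(list(coords = mds$coords,
                 variance_fraction = mds$variance_fraction,
                 stress = mds$stress, t_selected = t_sel, vne = vne,
                 labels = labels, spatial_weights = sw,
                 embedding_id = paste("emb", nrow(X), n_dims, knn, alpha,
                                      t_sel, signif(sum(X^2), 12),
                                      sep = "_"),
                 params = list(n_dims = n_dims, knn = knn, alpha = alpha,
                               t = t_sel, t_max = t_max)),
            class = "phate_embedding")
}

#' @export
print.phate_embedding <- function(x, ...) {
  cat(sprintf("diffusion-potential embedding: %d points x %d dims\n",
              nrow(x$coords), ncol(x$coords)))
  cat(sprintf("  t = %d, stress = %.4g\n", x$t_selected, x$stress))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}
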