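# Shared fixtures, built in code at test time.

# Small balanced schedule: 2 runs x 3 blocks x 13 trials (39 per
# condition), enough structure for GLM and embedding tests but an order
# of magnitude cheaper than a full session.
small_config <- function(seed = 1L) {
  task_config("long", n_runs = 2, seed = seed)
}

small_truth <- function(..., seed = 2L) {
  ground_truth(n_regions = 40, seed = seed, ...)
}

# Deterministic tiny point cloud for kernel/diffusion oracles.
tiny_points <- function(n = 8, p = 3, seed = 42) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# Straight-line re-computation of the alpha-decay kernel by loops.
brute_kernel <- function(X, knn, alpha) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  eps <- numeric(n)
  for (i in 1:n) eps[i] <- sort(D[i, -i])[knn]
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- 0.5 * exp(-(D[i, j] / eps[i])^alpha) +
      0.5 * exp(-(D[i, j] / eps[j])^alpha)
  }
  K
}

# Brute-force matrix power by repeated multiplication.
brute_power <- function(P, t) {
  out <- diag(nrow(P))
  for (k in seq_len(t)) out <- out %*% P
  out
}

# Straight-line potential distance from P^t.
brute_potential <- function(Pt, gamma = 1e-12) {
  n <- nrow(Pt)
  L <- log(Pt + gamma)
  U <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) U[i, j] <- sqrt(sum((L[i, ] - L[j, ])^2))
  U
}

# One-way within-subject ANOVA by explicit sums-of-squares loops.
brute_rm_anova <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  F <- (ss_cond / df1) / (ss_err / df2)
  list(F = F, df = c(df1, df2), p = pf(F, df1, df2, lower.tail = FALSE))
}
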