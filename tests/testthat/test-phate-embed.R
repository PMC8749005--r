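test_that("alpha-decay kernel satisfies its closed-form identities", {
  X <- tiny_points(20)
  aff <- alpha_decay_kernel(X, knn = 3, alpha = 35)
  K <- aff$K
  expect_equal(diag(K), rep(1, 20))
  expect_equal(K, t(K))
  expect_true(all(K >= 0 & K <= 1 + 1e-15))

  # d_ij = eps_i = eps_j  =>  K_ij = exp(-1)
  Xl <- matrix(c(0, 1, 2), ncol = 1)
  Kl <- alpha_decay_kernel(Xl, knn = 1, alpha = 35)$K
  expect_equal(Kl[1, 2], exp(-1))

  # widely separated clusters: inter-cluster affinity underflows
  tc <- make_toy_manifold("two_clusters", n_points = 40, ambient_dim = 5,
                          noise_sd = 0.02, seed = 4)
  Kc <- alpha_decay_kernel(tc$X, knn = 3, alpha = 35)$K
  expect_lt(max(Kc[tc$labels == 1, tc$labels == 2]), 1e-12)

  # duplicate-induced zero bandwidth is refused with advice
  dup <- rbind(X[1:5, ], X[rep(1, 5), ])
  expect_error(alpha_decay_kernel(dup, knn = 4), "zero bandwidth")
})

test_that("diffusion operator is row-stochastic with unit top eigenvalue", {
  X <- tiny_points(30)
  op <- diffusion_operator(alpha_decay_kernel(X, knn = 5))
  expect_equal(rowSums(op$P), rep(1, 30), tolerance = 1e-12)
  expect_true(all(op$P >= 0))
  expect_equal(max(abs(op$evalues)), 1, tolerance = 1e-10)
  expect_identical(diffusion_operator(diag(4))$P, diag(4))
})

test_that("entropy curve is nonincreasing and detects degenerate operators", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:25, 1)
    K <- crossprod(matrix(runif(n * n), n)) + diag(n)  # sym., nonneg.
    op <- diffusion_operator(K / max(K))
    H <- vne_curve(op, 40)
    expect_true(all(diff(H) <= 1e-10))
  }
  # two disconnected equal blocks: entropy flattens toward log(2)
  Kb <- matrix(0, 12, 12)
  Kb[1:6, 1:6] <- 0.5; Kb[7:12, 7:12] <- 0.5
  diag(Kb) <- 1
  Hb <- vne_curve(diffusion_operator(Kb), 200)
  expect_equal(Hb[200], log(2), tolerance = 1e-6)
  expect_error(select_t_vne(diffusion_operator(diag(8))), "no knee")
})

test_that("every stage matches a straight-line recomputation on small instances", {
  # dense neighborhoods keep every diffusion probability well above the
  # log floor, so the end-to-end comparison is numerically meaningful
  for (n in c(6, 8)) {
    X <- tiny_points(n, seed = 100 + n)
    knn <- n - 2; alpha <- 35; t_diff <- 3
    K_ref <- brute_kernel(X, knn, alpha)
    aff <- alpha_decay_kernel(X, knn = knn, alpha = alpha)
    expect_lt(max(abs(aff$K - K_ref)), 1e-8)

    P_ref <- K_ref / rowSums(K_ref)
    op <- diffusion_operator(aff)
    expect_lt(max(abs(op$P - P_ref)), 1e-8)

    Pt_ref <- brute_power(P_ref, t_diff)
    Pt <- neurotraj:::power_operator(op, t_diff)
    expect_lt(max(abs(Pt - Pt_ref)), 1e-8)

    U_ref <- brute_potential(Pt_ref)
    U <- potential_distance(op, t_diff)
    expect_lt(max(abs(U - U_ref)), 1e-8)
    expect_equal(diag(U), rep(0, n))
    expect_equal(U, t(U))
  }
})

test_that("disconnected graphs are refused with component sizes", {
  Kb <- matrix(0, 10, 10)
  Kb[1:4, 1:4] <- 0.6; Kb[5:10, 5:10] <- 0.6
  diag(Kb) <- 1
  op <- diffusion_operator(Kb)
  expect_error(potential_distance(op, 3), "2 connected components")
})

test_that("duplicated points share a diffusion profile and zero potential distance", {
  X <- tiny_points(7)
  X <- rbind(X, X[1, ])               # one duplicated point
  op <- diffusion_operator(alpha_decay_kernel(X, knn = 5))
  U <- potential_distance(op, 2)
  expect_lt(U[1, 8], 1e-10)
})

test_that("metric MDS recovers exactly embeddable configurations", {
  set.seed(11)
  X0 <- matrix(rnorm(40 * 3), 40, 3)
  U <- as.matrix(dist(X0))
  m <- metric_mds(U, n_dims = 3)
  expect_lte(m$stress, m$stress_initial + 1e-12)
  skip_if_not_installed("vegan")
  pro <- vegan::procrustes(X0, m$coords, symmetric = FALSE)
  rmsd <- sqrt(mean(rowSums((pro$X - pro$Yrot)^2)))
  expect_lt(rmsd, 1e-6)
})

test_that("metric MDS keeps duplicates coincident and rejects asymmetry", {
  X0 <- rbind(matrix(rnorm(20 * 3), 20, 3))
  X0 <- rbind(X0, X0[1, ])
  U <- as.matrix(dist(X0))
  m <- metric_mds(U, n_dims = 3)
  expect_lt(sqrt(sum((m$coords[21, ] - m$coords[1, ])^2)), 1e-8)
  Ua <- U; Ua[1, 2] <- Ua[1, 2] + 1
  expect_error(metric_mds(Ua, 2), "symmetric")
})

test_that("variance fractions are normalized and calibrated", {
  co <- cbind(rnorm(100), 0, 0)
  expect_equal(variance_explained(co), c(dim1 = 1, 0, 0),
               ignore_attr = TRUE)
  set.seed(12)
  iso <- matrix(rnorm(5000 * 5), 5000, 5)
  vf <- variance_explained(iso)
  expect_equal(sum(vf), 1, tolerance = 1e-12)
  expect_true(all(abs(vf - 0.2) < 0.02))
  expect_error(variance_explained(matrix(0, 5, 3)), "zero total variance")
})

test_that("spatial weights are correlations with the coordinate courses", {
  set.seed(13)
  co <- matrix(rnorm(702 * 3), 702, 3)
  V <- cbind(co[, 1],                        # copies coordinate 1
             matrix(rnorm(702 * 4), 702, 4), # pure noise regions
             0)                              # zero-variance region
  colnames(V) <- paste0("region", 1:6)
  resp <- neurotraj:::new_response_matrix(
    V, data.frame(trial = seq_len(702), condition = "1back",
                  accuracy = "correct", run = 1L, sample = 0L,
                  session = "baseline", participant = 1L),
    TR = 1, window_s = 9)
  expect_warning(W <- spatial_weights(resp, co), "zero-variance")
  expect_equal(dim(W), c(6, 3))
  expect_equal(unname(W[1, 1]), 1, tolerance = 1e-12)
  expect_true(all(abs(W[2:5, ]) < 0.1))
  expect_equal(W[6, ], c(dim1 = 0, dim2 = 0, dim3 = 0), ignore_attr = TRUE)
})

test_that("the embedding recovers a 1-D ordering from a noisy curve", {
  cur <- make_toy_manifold("noisy_curve", n_points = 200, ambient_dim = 10,
                           noise_sd = 0.2, seed = 14)  # SNR ~ 5
  emb <- phate_embed(cur$X, n_dims = 3, knn = 10, alpha = 35)
  rho <- cor(cur$ordering, rank(emb$coords[, 1]), method = "spearman")
  expect_gt(abs(rho), 0.95)
})

test_that("trajectory geometry is robust across the kernel parameter grid", {
  # fixed two-loop fixture; pairwise length ratios across the
  # alpha x knn grid vary by < 15%
  set.seed(15)
  th <- seq(0, 2 * pi, length.out = 80)[-80]
  loop <- cbind(cos(th), sin(th), 0.3 * sin(2 * th))
  X <- rbind(loop, 1.6 * loop) +
    matrix(rnorm(2 * 79 * 3, sd = 0.08), 2 * 79, 3)
  ratios <- c()
  for (alpha in c(35, 40, 45, 50)) for (knn in c(6, 8, 10)) {
    emb <- phate_embed(X, n_dims = 3, knn = knn, alpha = alpha)
    len <- function(P) sum(sqrt(rowSums(diff(P)^2)))
    ratios <- c(ratios, len(emb$coords[80:158, 1:3]) /
                          len(emb$coords[1:79, 1:3]))
  }
  expect_lt((max(ratios) - min(ratios)) / median(ratios), 0.15)
})
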