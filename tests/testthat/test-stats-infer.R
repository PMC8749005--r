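test_that("paired t reproduces the hand-computed statistic", {
  b <- c(1, 2, 3)
  a <- b + c(1, 2, 3)   # differences (1, 2, 3)
  res <- paired_t(a, b)
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_error(paired_t(b, b), "zero difference variance")
  # mean-zero differences with spread: t = 0, p = 1
  res0 <- paired_t(c(1, 2, 3), c(2, 2, 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
})

test_that("repeated-measures ANOVA matches explicit sums-of-squares", {
  set.seed(51)
  mat <- matrix(rnorm(6 * 3, mean = rep(c(0, 0.5, 1), each = 6)), 6, 3)
  res <- rm_anova(mat)
  ref <- brute_rm_anova(mat)
  expect_equal(res$statistic, ref$F, tolerance = 1e-10)
  expect_equal(res$df, ref$df)
  expect_equal(res$p, ref$p, tolerance = 1e-10)

  # exactly equal condition means: the condition sum of squares is zero
  flat <- matrix(rnorm(24), 8, 3)
  flat <- sweep(flat, 2, colMeans(flat))
  expect_lt(rm_anova(flat)$statistic, 1e-20)

  # missing cells are refused, no imputation
  expect_error(
    rm_anova(c(1, 2, 3, 4, 5), subject = c(1, 1, 2, 2, 3),
             f1 = c("a", "b", "a", "b", "a")),
    "missing cells")
})

test_that("two-way within-subject ANOVA reports the interaction", {
  set.seed(52)
  n <- 10
  dat <- expand.grid(subject = 1:n, f1 = c("l", "h"), f2 = c("x", "y", "z"))
  dat$y <- rnorm(nrow(dat)) +
    ifelse(dat$f1 == "h" & dat$f2 == "z", 4, 0)
  res <- rm_anova(dat$y, dat$subject, dat$f1, dat$f2)
  expect_equal(res$df, c(2, 18))
  expect_gt(res$statistic, 1)
})

test_that("pearson follows the t transform of r", {
  x <- c(1, 3, 4, 7, 9); y <- c(2, 5, 4, 8, 7)
  res <- pearson(x, y)
  r <- cor(x, y)
  t_ref <- r * sqrt((5 - 2) / (1 - r^2))
  expect_equal(res$estimate, r)
  expect_equal(res$statistic, t_ref, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_ref), 3), tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), y), "constant")
})

test_that("the Dunn-Clark z matches its formula and degenerates sensibly", {
  # independent pairs: c = 0, z from the plain Fisher contrast
  res <- compare_dependent_correlations(
    0.5, -0.5, c(r13 = 0, r14 = 0, r23 = 0, r24 = 0), n = 17)
  z_ref <- (atanh(0.5) - atanh(-0.5)) * sqrt((17 - 3) / 2)
  expect_equal(res$statistic, z_ref, tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(z_ref)), tolerance = 1e-12)

  # equal correlations with symmetric cross structure: z = 0, p = 1
  res0 <- compare_dependent_correlations(
    0.4, 0.4, c(r13 = 0.3, r14 = 0.2, r23 = 0.2, r24 = 0.3), n = 20)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  expect_error(compare_dependent_correlations(
    1, 0.5, c(r13 = 0, r14 = 0, r23 = 0, r24 = 0), 17), "Fisher")
  expect_error(compare_dependent_correlations(
    0.5, 0.2, c(r13 = 0, r14 = 0), 17), "cross")
  # the data wrapper agrees with the formula route
  set.seed(53)
  x1 <- rnorm(30); y1 <- 0.5 * x1 + rnorm(30)
  x2 <- rnorm(30); y2 <- -0.3 * x2 + rnorm(30)
  res_d <- compare_dependent_correlations_data(x1, y1, x2, y2)
  res_f <- compare_dependent_correlations(
    cor(x1, y1), cor(x2, y2),
    c(r13 = cor(x1, x2), r14 = cor(x1, y2),
      r23 = cor(y1, x2), r24 = cor(y1, y2)), 30)
  expect_equal(res_d$statistic, res_f$statistic)
})

test_that("BH adjustment matches the step-up rule by hand", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  # hand-computed mixed example: p(i) * m / i, cumulative minimum
  # sorted rule gives (0.02, 0.06, 0.0533..) before the step-up
  # cumulative minimum, which pulls rank 2 down to 4 * 0.04 / 3
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(bh_fdr(p), c(0.02, 4 * 0.04 / 3, 4 * 0.04 / 3, 0.8))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone in raw-p order and permutation-equivariant
  set.seed(54)
  q <- runif(20)
  adj <- bh_fdr(q)
  expect_true(all(diff(adj[order(q)]) >= -1e-15))
  perm <- sample(20)
  expect_equal(bh_fdr(q[perm]), adj[perm])
})
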