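test_that("the canonical HRF has the documented shape", {
  b <- hrf_basis(dt = 0.01)
  expect_equal(b$canonical[1], 0)
  expect_equal(b$time[which.max(b$canonical)], 5, tolerance = 0.011)
  expect_equal(max(b$canonical), 1)
  # decays below 1e-3 by the end of the 32-s support
  expect_lt(abs(b$canonical[length(b$canonical)]), 1e-3)
  # delay derivative integrates to ~0 over the decayed support
  expect_lt(abs(sum(b$delay_derivative) * b$dt), 1e-3)
  # three basis functions linearly independent on the grid
  B <- cbind(b$canonical, b$delay_derivative, b$dispersion_derivative)
  expect_equal(qr(B)$rank, 3)
})

test_that("design columns are the convolved basis, shift-invariant and superposing", {
  basis <- hrf_basis()
  mk_sched <- function(onsets) {
    neurotraj:::new_task_schedule(
      data.frame(onset = onsets, duration = 0.5,
                 condition = "1back", stimulus_id = 1,
                 is_target = FALSE, accuracy = "unset",
                 run = 1L, block = 1L, stringsAsFactors = FALSE),
      run_duration_s = 80, session_label = "test")
  }
  d1 <- build_design_matrix(mk_sched(0), basis, n_scans = 80)
  # single event at onset 0: canonical column equals h at integer lags
  h_tr <- basis$canonical[round(seq(0, 32, by = 1) / basis$dt) + 1]
  expect_equal(unname(d1$X[1:33, 1]), h_tr, tolerance = 1e-12)

  # two non-overlapping events: second column block is a shifted copy
  d2 <- build_design_matrix(mk_sched(c(0, 40)), basis, n_scans = 80)
  expect_equal(unname(d2$X[41:80, 4]), unname(d2$X[1:40, 1]),
               tolerance = 1e-12)

  # overlapping events superpose: joint design equals the sum of
  # single-event designs, column by column
  d3 <- build_design_matrix(mk_sched(c(0, 3)), basis, n_scans = 80)
  s1 <- build_design_matrix(mk_sched(0), basis, n_scans = 80)
  s2 <- build_design_matrix(mk_sched(3), basis, n_scans = 80)
  expect_equal(unname(d3$X[, 1:3]), unname(s1$X[, 1:3]), tolerance = 1e-12)
  expect_equal(unname(d3$X[, 4:6]), unname(s2$X[, 1:3]), tolerance = 1e-12)
  combined <- s1$X[, 1:3] + s2$X[, 1:3]
  expect_equal(unname(d3$X[, 1:3] + d3$X[, 4:6]), unname(combined),
               tolerance = 1e-12)

  expect_error(build_design_matrix(mk_sched(100), basis, n_scans = 80),
               "beyond scan end")
})

test_that("OLS matches the normal equations and recovers planted coefficients", {
  cfg <- small_config()
  sched <- label_accuracy(generate_schedule(cfg), 1)
  basis <- hrf_basis()
  n_scans <- round(attr(sched, "run_duration_s"))
  design <- build_design_matrix(sched, basis, n_scans = n_scans)

  # normal-equations oracle on a small instance
  set.seed(1)
  y <- rnorm(nrow(design$X))
  beta_qr <- qr.coef(design$qr, y)
  beta_ne <- solve(crossprod(design$X), crossprod(design$X, y))
  expect_equal(unname(beta_qr), unname(drop(beta_ne)), tolerance = 1e-10)

  # forward-simulate beta_can = 2 on every trial, zero derivatives
  n_trials <- nrow(sched)
  beta0 <- numeric(ncol(design$X))
  beta0[design$trial_columns[, 1]] <- 2
  ts <- matrix(design$X %*% beta0, nrow = 1)
  fit <- fit_trial_responses(ts, design)
  h9 <- neurotraj:::sample_basis_window(basis, 9, 1)[, 1]
  expect_equal(unname(fit$values[, 1]),
               rep(2 * h9, n_trials), tolerance = 1e-8)

  # zero input -> all-zero responses
  fit0 <- fit_trial_responses(matrix(0, 2, nrow(design$X)), design)
  expect_true(all(fit0$values == 0))

  # linearity in the data
  set.seed(2)
  ts2 <- matrix(rnorm(2 * nrow(design$X)), 2)
  fa <- fit_trial_responses(ts2, design)
  fb <- fit_trial_responses(3 * ts2, design)
  expect_equal(fb$values, 3 * fa$values, tolerance = 1e-10)
})

test_that("derivative regressors capture a latency-shifted response", {
  cfg <- small_config()
  sched <- label_accuracy(generate_schedule(cfg), 1)
  basis <- hrf_basis()
  n_scans <- round(attr(sched, "run_duration_s"))
  design <- build_design_matrix(sched, basis, n_scans = n_scans)
  # simulate responses shifted +1 s relative to the modeled onsets
  shifted <- sched
  shifted$onset <- shifted$onset + 1
  design_s <- build_design_matrix(shifted, basis, n_scans = n_scans)
  y <- design_s$X[, design_s$trial_columns[, 1]] %*%
    rep(1, nrow(sched))
  X_full <- design$X
  X_can <- design$X[, c(design$trial_columns[, 1],
                        ncol(design$X) - 1, ncol(design$X))]
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  expect_lt(rss(X_full), rss(X_can))
})

test_that("collinear designs are refused and the LSS fallback matches OLS when valid", {
  basis <- hrf_basis()
  mk <- function(onsets) neurotraj:::new_task_schedule(
    data.frame(onset = onsets, duration = 0.5, condition = "1back",
               stimulus_id = 1, is_target = FALSE, accuracy = "unset",
               run = 1L, block = 1L, stringsAsFactors = FALSE),
    run_duration_s = 150, session_label = "t")
  # duplicated onsets give identical trial columns
  dup <- build_design_matrix(mk(c(10, 10, 50)), basis, n_scans = 150)
  expect_error(fit_trial_responses(matrix(rnorm(150), 1), dup),
               "collinear")
  # planted coefficients representable by both designs are recovered
  # exactly by the joint fit and by least-squares-separate
  des <- build_design_matrix(mk(c(5, 50, 100)), basis, n_scans = 150)
  beta0 <- numeric(ncol(des$X))
  beta0[des$trial_columns[, 1]] <- c(2, -1, 0.5)  # canonical amplitudes
  beta0[ncol(des$X)] <- 1                         # run intercept
  Y <- matrix(des$X %*% beta0, ncol = 1)
  b_joint <- qr.coef(des$qr, Y)
  b_lss <- neurotraj:::fit_lss(des$X, Y, des)
  tcols <- as.vector(des$trial_columns)
  expect_equal(unname(b_lss[tcols, 1]), unname(b_joint[tcols, 1]),
               tolerance = 1e-8)
  expect_equal(unname(b_joint[tcols, 1]), beta0[tcols], tolerance = 1e-8)
})

test_that("concatenation preserves rows and rejects region mismatches", {
  labs <- function(n, sess) data.frame(
    trial = seq_len(n), condition = "1back", accuracy = "correct",
    run = 1L, sample = 0L, session = sess, participant = 1L)
  mk <- function(n, p, sess = "baseline") neurotraj:::new_response_matrix(
    matrix(rnorm(n * p), n, p,
           dimnames = list(NULL, paste0("region", 1:p))),
    labs(n, sess), TR = 1, window_s = 9)
  set.seed(3)
  a <- mk(702, 5); b <- mk(702, 5)
  cc <- concatenate_responses(list(a, b))
  expect_equal(nrow(cc$values), 1404)
  expect_identical(concatenate_responses(list(a))$values, a$values)
  expect_error(concatenate_responses(list(a, mk(10, 4))), "region sets")
  expect_error(concatenate_responses(list(a, mk(10, 5, "iPS"))),
               "multiple sessions")
  shared <- concatenate_responses(list(a, mk(10, 5, "iPS")), mode = "shared")
  expect_equal(nrow(shared$values), 712)
})
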