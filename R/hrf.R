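#' Informed hemodynamic basis set
#'
#' Canonical double-gamma hemodynamic response function plus its partial
#' derivatives with respect to onset delay and dispersion, sampled on a
#' regular grid over `[0, duration_s]`. The canonical is
#' `g(t; 6, 1) - g(t; 16, 1) / 6` (gamma densities, shape/scale), scaled
#' to unit peak. The delay derivative is the finite difference under a
#' 1-s onset shift; the dispersion derivative the finite difference
#' under a `0.01` change of the first gamma's scale. Both derivatives
#' share the canonical's normalization so the three columns live on one
#' amplitude scale.
#'
#' @param dt sampling step, seconds (default 0.1).
#' @param duration_s support of the response (default 32 s).
#' @param peak_delay,undershoot_delay gamma shapes (defaults 6 and 16).
#' @param dispersion,u_dispersion gamma scales (defaults 1 and 1).
#' @param undershoot_ratio peak/undershoot amplitude ratio (default 6).
#' @param delay_step finite-difference onset shift, seconds (default 1).
#' @param dispersion_step finite-difference scale change (default 0.01).
#' @return An `hrf_basis`: list with `time`, `canonical`,
#'   `delay_derivative`, `dispersion_derivative`, `dt`, `duration_s`.
#' @export
hrf_basis <- function(dt = 0.1, duration_s = 32,
                      peak_delay = 6, undershoot_delay = 16,
                      dispersion = 1, u_dispersion = 1,
                      undershoot_ratio = 6,
                      delay_step = 1, dispersion_step = 0.01) {
  if (dt <= 0) stopf("dt must be > 0")
  tt <- seq(0, duration_s, by = dt)
  dgam <- function(t, shape, scl) {
    out <- numeric(length(t))
    ok <- t > 0
    out[ok] <- stats::dgamma(t[ok], shape = shape, scale = scl)
    out
  }
  h0 <- dgam(tt, peak_delay, dispersion) -
    dgam(tt, undershoot_delay, u_dispersion) / undershoot_ratio
  peak <- max(h0)
  h <- h0 / peak
  h_shift <- (dgam(tt - delay_step, peak_delay, dispersion) -
                dgam(tt - delay_step, undershoot_delay, u_dispersion) /
                undershoot_ratio) / peak
  d_delay <- (h - h_shift) / delay_step
  h_disp <- (dgam(tt, peak_delay, dispersion + dispersion_step) -
               dgam(tt, undershoot_delay, u_dispersion) /
               undershoot_ratio) / peak
  d_disp <- (h - h_disp) / dispersion_step
  structure(list(time = tt, canonical = h,
                 delay_derivative = d_delay,
                 dispersion_derivative = d_disp,
                 dt = dt, duration_s = duration_s),
            class = "hrf_basis")
}

# Basis functions as a (length(time) x 3) matrix.
basis_matrix <- function(basis) {
  cbind(can = basis$canonical,
        delay = basis$delay_derivative,
        disp = basis$dispersion_derivative)
}

# Basis columns resampled at the TR grid over the response window.
# Samples sit at TR, 2 TR, ..., window_s: the onset instant itself is
# excluded because every basis function vanishes there by construction,
# which would pin all trials to one degenerate state-space point.
sample_basis_window <- function(basis, window_s, TR) {
  tau <- seq(TR, window_s, by = TR)
  idx <- round(tau / basis$dt) + 1L
  B <- basis_matrix(basis)
  B[idx, , drop = FALSE]
}
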