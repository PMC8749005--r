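#' Spectral kurtosis of a time series
#'
#' Short-time Fourier frames (Hann taper) give per-frequency powers
#' `P(m, f)`; the spectral kurtosis estimator is
#' `SK(f) = <P^2>_m / <P>_m^2 - 2`, which is ~0 for stationary Gaussian
#' signals, -1 for a deterministic line component, and elevated at
#' frequencies carrying transients. Frames are then screened:
#' frequencies with `SK > threshold` mark transient content (default
#' threshold: three times the Gaussian-null SK standard deviation
#' `sqrt(4 / M)` for `M` frames), and a frame is flagged when its mean
#' normalized power excess over those `m` frequencies exceeds three of
#' the frame score's own null standard deviations (`3 / sqrt(m)`).
#' Bins with negligible average power are excluded. The whole flagging
#' rule (windowing, taper, thresholds) is a reconstruction: standard
#' settings, all exposed as arguments.
#'
#' @param x numeric time series (length >= 4 windows).
#' @param window_len frame length in samples (default 64).
#' @param overlap fractional frame overlap in `[0, 1)` (default 0.5).
#' @param threshold flagging threshold in SK units; default
#'   `3 * sqrt(4 / M)`.
#' @return A `spectral_kurtosis` result: list with `sk` (per
#'   frequency), `freq` (cycles/sample), `flagged_frames`,
#'   `flagged_fraction`, `threshold`, `n_frames`, `frame_centers`.
#' @export
spectral_kurtosis <- function(x, window_len = 64, overlap = 0.5,
                              threshold = NULL) {
  n <- length(x)
  if (n < 4 * window_len) {
    stopf("series of length %d is shorter than 4 windows of %d",
          n, window_len)
  }
  if (stats::sd(x) == 0) stopf("constant signal: spectral kurtosis undefined")
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  hop <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq(1L, n - window_len + 1L, by = hop)
  M <- length(starts)
  # Hann taper
  w <- 0.5 * (1 - cos(2 * pi * seq_len(window_len) / (window_len + 1)))
  frames <- vapply(starts, function(s) x[s:(s + window_len - 1L)] * w,
                   numeric(window_len))
  spec <- stats::mvfft(frames)
  nb <- floor(window_len / 2)
  bins <- 2:nb                       # exclude DC and Nyquist
  P <- Mod(spec[bins, , drop = FALSE])^2   # freq x frames
  pbar <- rowMeans(P)
  # bins carrying a negligible share of the average per-bin power are
  # numerical silence: SK is undefined there in practice
  keep <- pbar > 1e-8 * mean(pbar)
  P <- P[keep, , drop = FALSE]
  pbar <- pbar[keep]
  sk <- rowMeans(P^2) / pbar^2 - 2
  if (is.null(threshold)) threshold <- 3 * sqrt(4 / M)
  transient_freqs <- which(sk > threshold)
  flagged <- rep(FALSE, M)
  if (length(transient_freqs)) {
    excess <- sweep(P[transient_freqs, , drop = FALSE], 1,
                    pbar[transient_freqs], "/") - 1
    score <- colMeans(excess)
    # the null frame score (mean of m unit-sd power excesses) has sd
    # 1/sqrt(m); flag frames exceeding 3 of its sds
    flagged <- score > 3 / sqrt(length(transient_freqs))
  }
  structure(list(sk = sk, freq = (bins[keep] - 1) / window_len,
                 flagged_frames = which(flagged),
                 flagged_fraction = mean(flagged),
                 threshold = threshold, n_frames = M,
                 frame_centers = starts + (window_len - 1) / 2,
                 window_len = window_len, overlap = overlap),
            class = "spectral_kurtosis")
}

#' Sharp-edge fractions of per-session stimulus series
#'
#' Runs [spectral_kurtosis()] on each session's convolved stimulus
#' time series and reports the flagged fraction in percent with a pass
#' flag at the < 7% criterion.
#'
#' @param stimulus_series named list of numeric series (one per session).
#' @param window_len,overlap,threshold passed to [spectral_kurtosis()].
#' @param pass_pct pass criterion in percent (default 7).
#' @return data.frame with `session`, `flagged_pct`, `n_frames`, `pass`.
#' @export
edge_fraction_report <- function(stimulus_series, window_len = 64,
                                 overlap = 0.5, threshold = NULL,
                                 pass_pct = 7) {
  stopifnot(is.list(stimulus_series), length(stimulus_series) >= 1)
  sessions <- names(stimulus_series)
  if (is.null(sessions)) sessions <- paste0("session", seq_along(stimulus_series))
  rows <- lapply(seq_along(stimulus_series), function(i) {
    sk <- spectral_kurtosis(stimulus_series[[i]], window_len = window_len,
                            overlap = overlap, threshold = threshold)
    data.frame(session = sessions[i],
               flagged_pct = 100 * sk$flagged_fraction,
               n_frames = sk$n_frames,
               pass = 100 * sk$flagged_fraction < pass_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concatenated convolved stimulus series for a schedule
#'
#' Convolves the session's stimulus onsets with the canonical HRF,
#' extracts each trial's response window (TR resolution), and
#' concatenates the windows in condition, accuracy, onset order — the
#' same trial-concatenated layout the trajectory analysis consumes, and
#' the series whose smoothness the spectral-kurtosis QC step screens.
#'
#' With `truncate = FALSE` the untruncated continuous regressor is
#' returned instead (runs concatenated at TR resolution), which is free
#' of windowing seams.
#'
#' @param schedule a `task_schedule`.
#' @param basis an [hrf_basis()] (default `hrf_basis()`).
#' @param TR repetition time (default 1).
#' @param window_s per-trial response window, seconds (default 9).
#' @param truncate cut the regressor into per-trial windows
#'   (default TRUE).
#' @return Numeric vector of `n_trials * window_s / TR` samples
#'   (truncated) or one value per scan (continuous).
#' @export
stimulus_series <- function(schedule, basis = hrf_basis(), TR = 1,
                            window_s = 9, truncate = TRUE) {
  run_dur <- attr(schedule, "run_duration_s")
  tau_idx <- round(seq(TR, window_s, by = TR) / basis$dt)
  if (!truncate) {
    out <- numeric(0)
    for (r in seq_along(run_dur)) {
      nf <- as.integer(round(run_dur[r] / basis$dt)) +
        length(basis$canonical)
      stick <- numeric(nf)
      rows <- which(schedule$run == r)
      stick[as.integer(round(schedule$onset[rows] / basis$dt)) + 1L] <- 1
      conv <- stats::convolve(stick, rev(basis$canonical),
                              type = "open")[seq_len(nf)]
      scan_idx <- as.integer(round(seq(0, by = TR,
                                       length.out = floor(run_dur[r] / TR)) /
                                     basis$dt)) + 1L
      out <- c(out, conv[scan_idx])
    }
    return(out)
  }
  seg <- vector("list", nrow(schedule))
  for (r in seq_along(run_dur)) {
    nf <- as.integer(round(run_dur[r] / basis$dt)) +
      length(basis$canonical) + max(tau_idx)
    stick <- numeric(nf)
    rows <- which(schedule$run == r)
    stick[as.integer(round(schedule$onset[rows] / basis$dt)) + 1L] <- 1
    conv <- stats::convolve(stick, rev(basis$canonical),
                            type = "open")[seq_len(nf)]
    for (j in rows) {
      onset_idx <- as.integer(round(schedule$onset[j] / basis$dt)) + 1L
      seg[[j]] <- conv[onset_idx + tau_idx]
    }
  }
  ord <- order(schedule$condition, schedule$accuracy, schedule$run,
               schedule$onset)
  unlist(seg[ord])
}
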