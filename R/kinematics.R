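#' Project movement onto its principal spatial axis
#'
#' Mean-centers a multi-axis position recording and projects it onto the
#' first principal axis of its spatial covariance, correcting for
#' deviations of the movement direction from the motion tracker's nominal
#' horizontal axis. The axis is oriented so its loading on the first
#' (nominal horizontal) axis is nonnegative.
#'
#' @param pos Numeric matrix, samples x spatial axes (>= 2 axes).
#' @return Numeric vector: the mean-centered projection; the axis loadings
#'   are attached as attribute `"axis"`.
#' @export
principal_axis_project <- function(pos) {
  pos <- as.matrix(pos)
  stopifnot_msg(nrow(pos) >= 2 && ncol(pos) >= 2,
                "need >= 2 samples and >= 2 spatial axes")
  cen <- scale(pos, center = TRUE, scale = FALSE)
  cv <- crossprod(cen) / (nrow(cen) - 1)
  stopifnot_msg(sum(diag(cv)) > .Machine$double.eps,
                "degenerate input: zero spatial variance, no principal axis")
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[1] < 0) v <- -v
  out <- as.numeric(cen %*% v)
  attr(out, "axis") <- v
  out
}

#' Self-other synchronization error series
#'
#' The error container used throughout the pipeline: the instantaneous
#' absolute difference between the two partners' positions on a common
#' principal axis, resampled to the EEG rate. All values are nonnegative.
#'
#' `error_series()` builds it from two position matrices: the principal
#' axis is fitted on the two partners' data *jointly* (stacked), so both
#' are projected onto one common spatial axis — the difference of
#' projections onto different axes would not be a spatial error. A
#' per-participant PCA is available with `joint = FALSE`.
#'
#' @param pos_a,pos_b Position matrices (samples x axes) at `fs_motion`, or
#'   already-projected numeric vectors (then the PCA step is skipped).
#' @param fs_motion Sampling rate of the positions, Hz.
#' @param fs_eeg Target sampling rate, Hz. Upsampling (the usual 240 -> 500
#'   Hz path) uses band-limited polyphase interpolation; a downsampling
#'   request is honored with a warning.
#' @param joint Fit one PCA on the stacked two-participant data (default)
#'   or one per participant.
#' @param trial_id,condition Optional labels carried along.
#' @return An object of class `error_series`: list with `values`
#'   (nonnegative numeric), `fs`, `trial_id`, `condition`.
#' @export
error_series <- function(pos_a, pos_b, fs_motion, fs_eeg = fs_motion,
                         joint = TRUE, trial_id = NA_character_,
                         condition = NA_character_) {
  if (is.matrix(pos_a) || is.data.frame(pos_a)) {
    pos_a <- as.matrix(pos_a); pos_b <- as.matrix(pos_b)
    stopifnot_msg(nrow(pos_a) == nrow(pos_b), "position traces must have equal length")
    if (joint) {
      both <- rbind(pos_a, pos_b)
      proj <- principal_axis_project(both)
      proj_a <- proj[seq_len(nrow(pos_a))]
      proj_b <- proj[-seq_len(nrow(pos_a))]
    } else {
      proj_a <- principal_axis_project(pos_a)
      proj_b <- principal_axis_project(pos_b)
    }
  } else {
    proj_a <- as.numeric(pos_a); proj_b <- as.numeric(pos_b)
  }
  compute_error(proj_a, proj_b, fs_motion, fs_eeg,
                trial_id = trial_id, condition = condition)
}

#' Compute the rectified self-other error from projected traces
#'
#' `|proj_a - proj_b|`, resampled from the motion rate to the EEG rate by
#' band-limited (Fourier) interpolation, which is amplitude-exact in band.
#' Interpolation ringing can produce tiny negative excursions near sharp
#' rectification points; these are clamped to zero to preserve
#' nonnegativity. The resampler's periodic extension makes the first/last
#' few samples a transient; at trial lengths of tens of seconds this is
#' absorbed by epoching.
#'
#' @param proj_a,proj_b Scalar position series on a common axis.
#' @param fs_motion,fs_eeg Input and output sampling rates, Hz.
#' @inheritParams error_series
#' @return An `error_series` object.
#' @export
compute_error <- function(proj_a, proj_b, fs_motion, fs_eeg = fs_motion,
                          trial_id = NA_character_, condition = NA_character_) {
  stopifnot_msg(length(proj_a) == length(proj_b),
                "projected traces must have equal length")
  stopifnot_msg(fs_motion > 0 && fs_eeg > 0, "sampling rates must be positive")
  err <- abs(proj_a - proj_b)
  if (fs_eeg != fs_motion) {
    if (fs_eeg < fs_motion) {
      rlang::warn("fs_eeg < fs_motion: downsampling the error (band-limited decimation)")
    }
    n_target <- round(length(proj_a) * fs_eeg / fs_motion)
    err <- pmax(fft_resample(err, n_target), 0)
  }
  structure(list(values = err, fs = fs_eeg,
                 trial_id = trial_id, condition = condition),
            class = "error_series")
}

#' @export
print.error_series <- function(x, ...) {
  cat("<error_series> ", length(x$values), " samples @ ", x$fs, " Hz",
      if (!is.na(x$condition)) paste0(" [", x$condition, "]") else "",
      "\n", sep = "")
  invisible(x)
}

# Analytic signal via the frequency-domain construction (one-sided
# spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Absolute rate of change of instantaneous movement frequency
#'
#' The movement-based control signal: instantaneous frequency is the
#' temporal derivative of the unwrapped analytic-signal (Hilbert) phase;
#' its derivative is taken again and rectified, so the output indexes
#' movement adjustments (accelerations and decelerations alike)
#' irrespective of direction. Both derivatives use a zero-phase local
#' polynomial (Savitzky-Golay) estimator over ~0.5 s, which suppresses the
#' sample-scale Hilbert-phase ripple that a plain finite difference would
#' amplify by the sampling rate. The first and last second are tapered
#' with a raised-cosine ramp to suppress the analytic-signal edge
#' artifacts.
#'
#' @param proj Zero-mean oscillatory scalar series (it is re-centered
#'   defensively; a constant input is rejected since its phase is
#'   undefined).
#' @param fs Sampling rate, Hz.
#' @param smooth_hz Zero-phase low-pass cutoff (Hz) applied to the
#'   instantaneous frequency before the second derivative; suppresses the
#'   analytic-signal ripple at twice the oscillation frequency. Set to
#'   `Inf` to disable.
#' @return An object of class `inst_freq_series`: list with `values`
#'   (|d f_inst / dt| in Hz/s), `fs`, and the intermediate instantaneous
#'   frequency as attribute `"freq_hz"`.
#' @export
instantaneous_freq_change <- function(proj, fs, smooth_hz = 0.5) {
  x <- as.numeric(proj)
  stopifnot_msg(length(x) >= round(2 * fs), "need at least 2 s of signal")
  x <- x - mean(x)
  stopifnot_msg(sd(x) > .Machine$double.eps,
                "constant input: instantaneous phase undefined")
  z <- analytic_signal(x)
  phase <- signal::unwrap(Arg(z))
  n <- length(phase)
  # Savitzky-Golay derivatives: a raw sample-wise difference multiplies
  # the Hilbert-phase ripple by fs, swamping the slow frequency
  # adjustments of interest; a local polynomial derivative over ~0.5 s
  # differentiates and low-passes in one zero-phase step.
  win <- max(5L, round(0.5 * fs))
  if (win %% 2 == 0) win <- win + 1L
  sg_deriv <- function(v) {
    as.numeric(signal::sgolayfilt(v, p = 3, n = win, m = 1, ts = 1 / fs))
  }
  f_inst <- sg_deriv(phase) / (2 * pi)
  # the discrete analytic signal carries a small ripple at twice the
  # oscillation frequency; frequency *adjustments* live well below the
  # movement rate, so the instantaneous frequency is low-passed
  # (zero-phase) before the second derivative
  if (is.finite(smooth_hz) && smooth_hz < fs / 2) {
    # exact zero-phase low-pass: detrend (so the periodic extension has no
    # step), zero the Fourier bins above the cutoff, restore the trend
    idx <- seq_along(f_inst)
    beta <- cov(idx, f_inst) / var(idx)
    trend <- mean(f_inst) + beta * (idx - mean(idx))
    r <- f_inst - trend
    R <- fft(r)
    fr <- (idx - 1) / n * fs
    fr <- pmin(fr, fs - fr)
    R[fr > smooth_hz] <- 0
    f_smooth <- trend + Re(fft(R, inverse = TRUE)) / n
  } else {
    f_smooth <- f_inst
  }
  dfdt <- abs(sg_deriv(f_smooth))
  edge <- min(round(fs), floor(n / 2))
  if (edge > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
    dfdt[seq_len(edge)] <- dfdt[seq_len(edge)] * ramp
    dfdt[(n - edge + 1):n] <- dfdt[(n - edge + 1):n] * rev(ramp)
  }
  structure(list(values = dfdt, fs = fs), class = "inst_freq_series",
            freq_hz = f_inst)
}
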