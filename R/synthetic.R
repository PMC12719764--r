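#' Configuration for a synthetic dyad trial
#'
#' Describes one trial of a dyadic improvised-synchronization task: two
#' partners produce near-sinusoidal horizontal forearm oscillations whose
#' frequency and amplitude drift slowly ("improvisation"), with asymmetric
#' phase coupling that depends on the leadership condition. EEG channels are
#' simulated as a noisy, time-shifted linear image of the self-other error
#' on top of a 1/f background, so the ground-truth tracking lag and
#' signal-to-noise ratio are known exactly.
#'
#' @param duration_s Trial duration in seconds (task trials are 180 s).
#' @param fs_motion Motion-capture sampling rate, Hz (240).
#' @param fs_eeg EEG sampling rate after decimation, Hz (500).
#' @param condition Leadership role: `"follower"` (partner B adapts to A),
#'   `"leader"` (A adapts to B), or `"joint"` (symmetric coupling at half
#'   strength each).
#' @param base_freq Mean oscillation rate, Hz (movement is ~0.5-1.5 Hz).
#' @param drift_std Random-walk scale of the instantaneous movement
#'   frequency, Hz per sqrt(s); also scales the slow amplitude drift. Zero
#'   gives strictly periodic movement.
#' @param coupling_strength Phase-attraction gain in `[0, 1]`; 0 decouples
#'   the partners, 1 is strong adaptive coupling.
#' @param follower_delay_s Visuomotor reaction delay of the adapting
#'   partner, seconds.
#' @param tracking_lag_s Ground-truth lag of the EEG error-tracking
#'   component, seconds; positive means the EEG lags the error.
#' @param tracking_snr Power of the tracking component divided by the power
#'   of the 1/f background in the tracking channels; `Inf` gives noiseless
#'   tracking channels.
#' @param tracking_band_hz Upper edge (Hz) of the band the EEG actually
#'   tracks: the error image embedded in tracking channels is low-passed
#'   below this frequency. `Inf` (default) embeds the full-band error.
#' @param n_channels Number of EEG channels per participant.
#' @param n_tracking_channels How many of those channels carry the tracking
#'   component (the rest are background only).
#' @param noise_std Additive white positional noise, as a fraction of the
#'   movement amplitude.
#' @param noise_exponent Spectral exponent of the EEG background (power ~
#'   1/f^exponent).
#' @param seed Integer seed; every stochastic component draws from a
#'   substream derived from it (see [derive_seed()]).
#' @return An object of class `dyad_config`.
#' @export
dyad_config <- function(duration_s = 180, fs_motion = 240, fs_eeg = 500,
                        condition = c("follower", "leader", "joint"),
                        base_freq = 1, drift_std = 0.05,
                        coupling_strength = 0.8, follower_delay_s = 0.2,
                        tracking_lag_s = 0.1, tracking_snr = 1,
                        tracking_band_hz = Inf,
                        n_channels = 8, n_tracking_channels = 2,
                        noise_std = 0.01, noise_exponent = 1, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot_msg(is_scalar_number(duration_s) && duration_s > 0,
                "duration_s must be a positive number")
  stopifnot_msg(fs_motion > 0 && fs_eeg > 0, "sampling rates must be positive")
  stopifnot_msg(coupling_strength >= 0 && coupling_strength <= 1,
                "coupling_strength must lie in [0, 1]")
  stopifnot_msg(abs(tracking_lag_s) < 2,
                "tracking_lag_s magnitude must be below half the lag-scan range (2 s)")
  stopifnot_msg(tracking_snr >= 0, "tracking_snr must be nonnegative")
  stopifnot_msg(n_tracking_channels <= n_channels,
                "n_tracking_channels cannot exceed n_channels")
  structure(list(
    duration_s = duration_s, fs_motion = fs_motion, fs_eeg = fs_eeg,
    condition = condition, base_freq = base_freq, drift_std = drift_std,
    coupling_strength = coupling_strength, follower_delay_s = follower_delay_s,
    tracking_lag_s = tracking_lag_s, tracking_snr = tracking_snr,
    tracking_band_hz = tracking_band_hz,
    n_channels = as.integer(n_channels),
    n_tracking_channels = as.integer(n_tracking_channels),
    noise_std = noise_std, noise_exponent = noise_exponent,
    seed = as.integer(seed)
  ), class = "dyad_config")
}

# Reflected Gaussian random walk, kept inside [lo, hi].
reflected_walk <- function(n, start, step_sd, lo, hi) {
  x <- start + cumsum(rnorm(n, sd = step_sd))
  rng <- hi - lo
  y <- (x - lo) %% (2 * rng)
  lo + ifelse(y > rng, 2 * rng - y, y)
}

#' Simulate dyadic improvised oscillatory movement
#'
#' Two phase oscillators: partner A's phase advances at an instantaneous
#' frequency performing a reflected random walk around `base_freq`; the
#' adapting partner's phase is pulled toward the other's delayed phase with
#' gain proportional to `coupling_strength` (Euler integration at
#' `fs_motion`). In the `joint` condition both partners adapt at half
#' strength. Positions are amplitude-modulated sinusoids embedded in two
#' spatial axes (a fixed small rotation off the nominal horizontal plus an
#' elliptical minor component) with additive white positional noise.
#'
#' @param config A [dyad_config()].
#' @return A list with `pos_a`, `pos_b` (`n x 2` position matrices at
#'   `fs_motion`) carrying the generating phases as attributes `phase_a`,
#'   `phase_b`, and instantaneous frequencies `freq_a`, `freq_b` (Hz).
#' @export
simulate_movement <- function(config) {
  stopifnot_msg(inherits(config, "dyad_config"), "config must be a dyad_config")
  n <- round(config$duration_s * config$fs_motion)
  dt <- 1 / config$fs_motion
  set.seed(derive_seed(config$seed, "movement"))

  f0 <- config$base_freq
  step <- config$drift_std * sqrt(dt)
  f_a <- if (step > 0) reflected_walk(n, f0, step, max(0.1, f0 / 4), 3 * f0) else rep(f0, n)
  f_b <- if (step > 0) reflected_walk(n, f0, step, max(0.1, f0 / 4), 3 * f0) else rep(f0, n)

  d_samp <- max(0L, round(config$follower_delay_s * config$fs_motion))
  gain <- config$coupling_strength * 2 * pi  # rad/s phase attraction
  k_a <- switch(config$condition, follower = 0, leader = gain, joint = gain / 2)
  k_b <- switch(config$condition, follower = gain, leader = 0, joint = gain / 2)

  phi_a <- phi_b <- numeric(n)
  phi_b[1] <- 2 * pi * rnorm(1, sd = if (config$coupling_strength > 0) 0.05 else 0.25)
  for (t in seq_len(n - 1)) {
    td <- max(1L, t - d_samp)
    dphi_a <- 2 * pi * f_a[t] + k_a * sin(phi_b[td] - phi_a[t])
    dphi_b <- 2 * pi * f_b[t] + k_b * sin(phi_a[td] - phi_b[t])
    phi_a[t + 1] <- phi_a[t] + dphi_a * dt
    phi_b[t + 1] <- phi_b[t] + dphi_b * dt
  }

  amp_step <- config$drift_std * sqrt(dt)
  amp_a <- if (amp_step > 0) reflected_walk(n, 1, amp_step, 0.4, 1.6) else rep(1, n)
  amp_b <- if (amp_step > 0) reflected_walk(n, 1, amp_step, 0.4, 1.6) else rep(1, n)

  embed_pos <- function(amp, phi) {
    x <- amp * sin(phi)               # main (horizontal) component
    w <- 0.05 * amp * sin(phi + pi / 3) # small elliptical minor component
    theta <- 0.15                     # fixed tilt off the nominal horizontal
    p <- cbind(x * cos(theta) - w * sin(theta),
               x * sin(theta) + w * cos(theta))
    if (config$noise_std > 0) {
      p <- p + matrix(rnorm(2 * length(x), sd = config$noise_std), ncol = 2)
    }
    p
  }
  pos_a <- embed_pos(amp_a, phi_a)
  pos_b <- embed_pos(amp_b, phi_b)
  attr(pos_a, "phase") <- phi_a; attr(pos_a, "freq") <- f_a
  attr(pos_b, "phase") <- phi_b; attr(pos_b, "freq") <- f_b
  list(pos_a = pos_a, pos_b = pos_b)
}

# 1/f^alpha Gaussian background, unit variance, mean zero.
pink_noise <- function(n, exponent = 1) {
  wn <- rnorm(n)
  x <- fft(wn)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up
  f <- pmin(f, n - f + 1)            # fold to two-sided frequency index
  x <- x * f^(-exponent / 2)
  x[1] <- 0
  y <- Re(fft(x, inverse = TRUE)) / n
  as.numeric(scale(y))
}

#' Simulate EEG channels tracking the self-other error
#'
#' The first `n_tracking_channels` channels contain the (demeaned) error
#' signal shifted by `tracking_lag_s` (positive lag: EEG lags the error),
#' scaled so the ratio of tracking-component power to background power
#' equals `tracking_snr`; the remaining channels are 1/f background only.
#' All channels are mean-centered. With `tracking_snr = Inf` the tracking
#' channels are the shifted error exactly (unit-variance scaled).
#'
#' @param error An [error_series()] object or numeric vector sampled at
#'   `config$fs_eeg`.
#' @param config A [dyad_config()].
#' @param seed_key Extra key(s) mixed into the seed derivation so the two
#'   participants of a dyad get independent backgrounds.
#' @return A `n_channels x n_time` numeric matrix with rownames
#'   `ch01, ch02, ...`; tracking channels come first.
#' @export
simulate_eeg <- function(error, config, seed_key = "eeg") {
  vals <- if (inherits(error, "error_series")) error$values else as.numeric(error)
  n <- length(vals)
  lag_samp <- round(config$tracking_lag_s * config$fs_eeg)
  stopifnot_msg(abs(lag_samp) < n, "tracking_lag_s exceeds the error duration")
  set.seed(derive_seed(config$seed, seed_key))
  err_c <- vals - mean(vals)
  band <- config$tracking_band_hz %||% Inf
  if (is.finite(band) && band < config$fs_eeg / 2) {
    X <- fft(err_c)
    fr <- (seq_along(err_c) - 1) / length(err_c) * config$fs_eeg
    fr <- pmin(fr, config$fs_eeg - fr)
    X[fr > band] <- 0
    err_c <- Re(fft(X, inverse = TRUE)) / length(err_c)
  }
  shifted <- circ_shift(err_c, lag_samp)
  nch <- config$n_channels
  eeg <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch)) {
    bg <- pink_noise(n, config$noise_exponent)
    if (ch <= config$n_tracking_channels) {
      if (is.infinite(config$tracking_snr)) {
        eeg[ch, ] <- shifted / sd(shifted)
      } else if (config$tracking_snr > 0) {
        a <- sqrt(config$tracking_snr * var(bg) / var(shifted))
        eeg[ch, ] <- a * shifted + bg
      } else {
        eeg[ch, ] <- bg
      }
    } else {
      eeg[ch, ] <- bg
    }
  }
  eeg <- eeg - rowMeans(eeg)
  rownames(eeg) <- sprintf("ch%02d", seq_len(nch))
  eeg
}

#' Simulate one complete dyad trial
#'
#' Runs the movement simulation, derives the self-other error (joint
#' principal-axis projection, rectified difference, resampling to the EEG
#' rate), and synthesizes EEG for both participants.
#'
#' @param config A [dyad_config()].
#' @return An object of class `dyad_trial`: a list with `pos_a`, `pos_b`,
#'   `eeg_a`, `eeg_b`, `error` (an [error_series()]), `condition`, and
#'   `ground_truth` (the config).
#' @export
simulate_dyad_trial <- function(config) {
  mv <- simulate_movement(config)
  err <- error_series(mv$pos_a, mv$pos_b,
                      fs_motion = config$fs_motion, fs_eeg = config$fs_eeg,
                      condition = config$condition)
  eeg_a <- simulate_eeg(err, config, seed_key = "eeg_a")
  eeg_b <- simulate_eeg(err, config, seed_key = "eeg_b")
  stopifnot_msg(all(is.finite(mv$pos_a)) && all(is.finite(eeg_a)),
                "simulated trial contains non-finite values")
  structure(list(pos_a = mv$pos_a, pos_b = mv$pos_b,
                 eeg_a = eeg_a, eeg_b = eeg_b, error = err,
                 condition = config$condition, ground_truth = config),
            class = "dyad_trial")
}

#' Simulate a participant's set of trials in one condition
#'
#' Convenience wrapper producing `n_trials` independent trials sharing one
#' configuration (per-trial seeds derived from `config$seed`), as recorded
#' in the motivating task design (4 trials per leadership condition).
#'
#' @param config A [dyad_config()].
#' @param n_trials Number of trials (default 4).
#' @return A list of `dyad_trial` objects.
#' @export
simulate_condition_trials <- function(config, n_trials = 4) {
  lapply(seq_len(n_trials), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "trial", i)
    simulate_dyad_trial(cfg)
  })
}

#' @export
print.dyad_config <- function(x, ...) {
  cat("<dyad_config> ", x$condition, ", ", x$duration_s, " s, base ",
      x$base_freq, " Hz, coupling ", x$coupling_strength,
      ", tracking lag ", x$tracking_lag_s, " s, snr ", x$tracking_snr,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.dyad_trial <- function(x, ...) {
  cat("<dyad_trial> ", x$condition, ": motion ", nrow(x$pos_a), " x 2 @ ",
      x$ground_truth$fs_motion, " Hz; EEG ", nrow(x$eeg_a), " ch x ",
      ncol(x$eeg_a), " @ ", x$ground_truth$fs_eeg, " Hz\n", sep = "")
  invisible(x)
}
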