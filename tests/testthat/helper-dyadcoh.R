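# Shared fixtures: small, fast configurations used across test files.
# Sampling rates and durations are reduced from the task's nominal values
# (180 s trials, 500 Hz EEG) purely to keep the suite quick; the defaults
# of dyad_config() remain the nominal study conditions.

quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(duration_s = 30, fs_motion = 100, fs_eeg = 100,
                   n_channels = 3, n_tracking_channels = 1,
                   tracking_snr = 2, tracking_lag_s = 0.1, seed = 42L)
  do.call(dyad_config, utils::modifyList(defaults, args))
}

# A trial reduced to the eeg/error pair the spectral stages consume.
pair_of <- function(trial, side = "a") {
  list(eeg = if (side == "a") trial$eeg_a else trial$eeg_b,
       error = trial$error)
}

# Band-limited noise: white noise low-passed below f_hi (Hz).
lowpass_noise <- function(n, fs, f_hi, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  bf <- signal::butter(4, f_hi / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}
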