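# Time-lagged coherence: band-averaged EEG-error coherence as a function
# of the time shift applied to the error series. The peak of the profile
# estimates the latency of neural tracking.
#
# Sign convention: at lag tau, EEG at time t is compared with error at
# time t - tau, so a positive peak lag means brain modulations *lag
# behind* the self-other error, and a negative peak lag means they run
# ahead of it.

#' Uniform lag grid
#'
#' @param lag_min,lag_max Range endpoints, seconds (defaults -2 and 2).
#' @param step Grid step, seconds (default 0.02). Endpoints must be
#'   multiples of the step; the default grid has 201 lags and contains 0.
#' @return Numeric vector of lags in seconds.
#' @export
lag_grid <- function(lag_min = -2, lag_max = 2, step = 0.02) {
  stopifnot_msg(step > 0, "step must be positive")
  stopifnot_msg(lag_max >= lag_min, "lag_max must be >= lag_min")
  k_min <- lag_min / step
  k_max <- lag_max / step
  stopifnot_msg(abs(k_min - round(k_min)) < 1e-9 &&
                  abs(k_max - round(k_max)) < 1e-9,
                "range endpoints must be multiples of the step")
  seq(round(k_min), round(k_max)) * step
}

# Smallest |lag| wins ties; negative before positive at equal |lag|.
peak_pick <- function(lags, coh) {
  ok <- is.finite(coh)
  if (!any(ok)) return(list(peak_coh = NA_real_, peak_lag = NA_real_))
  mx <- max(coh[ok])
  cand <- lags[ok][coh[ok] >= mx - 1e-12]
  cand <- cand[order(abs(cand), cand)]
  list(peak_coh = mx, peak_lag = cand[1])
}

profile_peaks <- function(df) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(df), .data$group),
    peak_coh = peak_pick(.data$lag, .data$coherence)$peak_coh,
    peak_lag = peak_pick(.data$lag, .data$coherence)$peak_lag,
    .groups = "drop")
}

new_lag_profile <- function(df, fs, band) {
  structure(df, class = c("lag_profile", class(tibble::tibble())),
            fs = fs, band = band)
}

#' Time-lagged band-averaged coherence profile
#'
#' For each lag on the grid, the error series is shifted against the EEG by
#' an exact integer number of samples (each 0.02 s step is 10 samples at
#' 500 Hz, so no interpolation is involved), the epochs that fall entirely
#' inside the overlap region are retained, coherence is computed with the
#' standard multitaper settings pooled across trials, and averaged within
#' the analysis band (0-6 Hz by default — the band showing above-chance
#' tracking at the sensor level). The EEG-side tapered Fourier coefficients
#' are computed once per trial and reused across all lags.
#'
#' @param trials List of trials (each with `$eeg`, `$error`) or a single
#'   such trial.
#' @param fs Sampling rate, Hz; every lag must be an integer number of
#'   samples at this rate.
#' @param lags Lag grid from [lag_grid()], seconds.
#' @param band Two-element band for the coherence average, Hz.
#' @param epoch_len_s,overlap,n_tapers,taper Spectral settings as in
#'   [mt_csd()].
#' @return A tibble of class `lag_profile` with columns `group` (channel),
#'   `lag` (s), `coherence`; per-group peaks are available via
#'   [peaks()] / [glance()].
#' @export
lagged_coherence <- function(trials, fs, lags = lag_grid(), band = c(0, 6),
                             epoch_len_s = 5, overlap = 0.5, n_tapers = 3,
                             taper = "dpss") {
  if (!is.null(trials$eeg)) trials <- list(trials)
  lag_samp <- round(lags * fs)
  stopifnot_msg(max(abs(lag_samp / fs - lags)) < 1e-9,
                "every lag must be an integer number of samples at fs")
  nper <- round(epoch_len_s * fs)
  f_band_max <- band[2]

  prep <- lapply(trials, function(tr) {
    eeg <- as_signal_matrix(tr$eeg)
    err <- if (inherits(tr$error, "error_series")) tr$error$values else as.numeric(tr$error)
    stopifnot_msg(ncol(eeg) == length(err), "EEG and error lengths differ")
    stopifnot_msg(max(abs(lag_samp)) < ncol(eeg) - nper,
                  "lag range leaves no complete epoch inside the trial")
    starts <- epoch_starts(ncol(eeg), fs, epoch_len_s, overlap)
    ce <- mt_coef(eeg, fs, epoch_len_s, overlap, n_tapers, f_band_max, taper,
                  starts = starts)
    list(ce = ce, err = err, starts = starts, n = ncol(eeg))
  })

  ch_names <- prep[[1]]$ce$channel_names
  freqs <- prep[[1]]$ce$freqs
  in_band <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9

  coh_by_lag <- vapply(seq_along(lags), function(li) {
    s <- lag_samp[li]
    ses <- lapply(prep, function(p) {
      # error segment for epoch starting at t is taken at t - s
      err_starts <- p$starts - s
      keep <- err_starts >= 1L & (err_starts + nper - 1L) <= p$n
      stopifnot_msg(any(keep), "no epoch fits inside the lag overlap region")
      ce_x <- p$ce
      tap <- ce_x$n_tapers
      cols <- as.vector(vapply(which(keep), function(ei)
        ((ei - 1L) * tap + 1L):(ei * tap), integer(tap)))
      ce_x$coef <- ce_x$coef[, cols, , drop = FALSE]
      ce_x$n_epochs <- sum(keep)
      ce_y <- mt_coef(matrix(p$err, nrow = 1), fs, epoch_len_s, overlap,
                      n_tapers, f_band_max, taper,
                      starts = err_starts[keep])
      csd_from_coef(ce_x, ce_y)
    })
    cs <- coherence(pool_spectra(ses))
    ba <- band_average(cs, band[1], band[2])
    ba$coherence[match(ch_names, ba$channel)]
  }, numeric(length(ch_names)))
  # coh_by_lag: channels x lags
  coh_by_lag <- matrix(coh_by_lag, nrow = length(ch_names))

  df <- tibble::tibble(
    group = rep(ch_names, times = length(lags)),
    lag = rep(lags, each = length(ch_names)),
    coherence = as.vector(coh_by_lag)
  )
  new_lag_profile(df, fs = fs, band = band)
}

#' Peak magnitude and latency of a lag profile
#'
#' Maximum band-averaged coherence over the stored lag grid and the lag at
#' which it occurs, per group. Ties are broken toward the smallest absolute
#' lag, then negative before positive.
#'
#' @param profile A `lag_profile`.
#' @return Tibble `group, peak_coh, peak_lag`.
#' @export
peaks <- function(profile) {
  stopifnot_msg(inherits(profile, "lag_profile"), "profile must be a lag_profile")
  profile_peaks(profile)
}

#' Average lag profiles over channel groups
#'
#' Averages the per-channel profiles within named channel groups (the
#' sensor-space analogue of region-of-interest averaging), then extracts
#' the peak on each *averaged* profile.
#'
#' @param profile A per-channel `lag_profile`.
#' @param groups Named list mapping group labels to character vectors of
#'   member channels; groups must be non-empty and reference existing
#'   channels.
#' @return A `lag_profile` with one profile per group.
#' @export
group_average <- function(profile, groups) {
  stopifnot_msg(inherits(profile, "lag_profile"), "profile must be a lag_profile")
  stopifnot_msg(length(groups) >= 1 && !is.null(names(groups)),
                "groups must be a named list")
  have <- unique(profile$group)
  rows <- purrr::map2_dfr(names(groups), groups, function(gname, members) {
    stopifnot_msg(length(members) >= 1, paste0("empty group: ", gname))
    stopifnot_msg(all(members %in% have),
                  paste0("unknown channels in group ", gname))
    sub <- tibble::as_tibble(profile)[profile$group %in% members, ]
    agg <- dplyr::summarise(dplyr::group_by(sub, .data$lag),
                            coherence = mean(.data$coherence, na.rm = TRUE),
                            .groups = "drop")
    tibble::tibble(group = gname, lag = agg$lag, coherence = agg$coherence)
  })
  new_lag_profile(rows, fs = attr(profile, "fs"), band = attr(profile, "band"))
}

#' Movement-alignment control lag scan
#'
#' The same time-lagged coherence computed between the absolute rate of
#' change of a participant's instantaneous movement frequency and the
#' self-other error. If condition differences in the EEG peak lag were
#' driven by movement alignment rather than neural tracking, this control
#' would show matching differences. A near-constant control signal has no
#' defined coherence; it is flagged by returning all-`NA` profiles.
#'
#' @param ifs An [instantaneous_freq_change()] result (or numeric vector).
#' @param error [error_series()] or numeric vector at the same rate.
#' @param fs Sampling rate, Hz.
#' @inheritParams lagged_coherence
#' @return A `lag_profile` with the single group `"movement"`.
#' @export
movement_control_lagscan <- function(ifs, error, fs, lags = lag_grid(),
                                     band = c(0, 6), epoch_len_s = 5,
                                     overlap = 0.5, n_tapers = 3) {
  vals <- if (inherits(ifs, "inst_freq_series")) ifs$values else as.numeric(ifs)
  m <- matrix(vals, nrow = 1, dimnames = list("movement", NULL))
  lagged_coherence(list(list(eeg = m, error = error)), fs = fs, lags = lags,
                   band = band, epoch_len_s = epoch_len_s, overlap = overlap,
                   n_tapers = n_tapers)
}
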