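# Multitaper cross-spectral machinery.
#
# Spectra are estimated on short overlapping epochs, each demeaned and
# multiplied by K orthonormal Slepian tapers; auto- and cross-spectral
# densities are pooled (averaged) over all epochs x tapers, and across
# trials of a condition, before coherence is formed. Coherence of the
# pooled cross-spectral density — not a mean of per-trial coherences — is
# the estimator throughout.

#' Epoch start indices
#'
#' Consecutive windows of `epoch_len_s` advancing by
#' `epoch_len_s * (1 - overlap)`; a trailing partial window is dropped.
#'
#' @param n_samples Series length in samples.
#' @param fs Sampling rate, Hz.
#' @param epoch_len_s Epoch length, seconds (default 5).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return Integer vector of 1-based start indices.
#' @export
epoch_starts <- function(n_samples, fs, epoch_len_s = 5, overlap = 0.5) {
  stopifnot_msg(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  nper <- round(epoch_len_s * fs)
  stopifnot_msg(n_samples >= nper, "series shorter than one epoch")
  step <- round(epoch_len_s * (1 - overlap) * fs)
  stopifnot_msg(step >= 1, "epoch step must be at least one sample")
  seq.int(1L, n_samples - nper + 1L, by = step)
}

#' Cut a series into overlapping epochs
#'
#' @inheritParams epoch_starts
#' @param x Numeric vector.
#' @return Matrix, `epoch_len_s * fs` samples x number of epochs.
#' @export
epoch_signal <- function(x, fs, epoch_len_s = 5, overlap = 0.5) {
  starts <- epoch_starts(length(x), fs, epoch_len_s, overlap)
  nper <- round(epoch_len_s * fs)
  vapply(starts, function(s) x[s:(s + nper - 1L)], numeric(nper))
}

spectral_window <- function(nper, n_tapers, taper = c("dpss", "hanning")) {
  taper <- match.arg(taper)
  if (taper == "dpss") {
    dpss_tapers(nper, nw = (n_tapers + 1) / 2, k = n_tapers)
  } else {
    h <- 0.5 * (1 - cos(2 * pi * seq_len(nper) / (nper + 1)))
    matrix(h / sqrt(sum(h^2)), ncol = 1)
  }
}

# Tapered Fourier coefficients for a channels x time matrix.
# Returns freqs plus a complex array [n_freq, n_epochs * n_tapers, n_ch].
# Optional `starts` overrides the epoch grid (used by the lag scan).
mt_coef <- function(data, fs, epoch_len_s = 5, overlap = 0.5, n_tapers = 3,
                    f_max = 10, taper = "dpss", starts = NULL) {
  data <- as_signal_matrix(data)
  nper <- round(epoch_len_s * fs)
  if (is.null(starts)) starts <- epoch_starts(ncol(data), fs, epoch_len_s, overlap)
  g <- spectral_window(nper, n_tapers, taper)
  k <- ncol(g)
  df <- 1 / epoch_len_s
  n_keep <- min(floor(f_max / df), floor(nper / 2)) + 1L
  freqs <- (seq_len(n_keep) - 1L) * df
  nch <- nrow(data)
  coef <- array(complex(real = 0), dim = c(n_keep, length(starts) * k, nch))
  for (ei in seq_along(starts)) {
    seg <- data[, starts[ei]:(starts[ei] + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)            # demean each epoch
    segt <- t(seg)                        # nper x nch
    for (ki in seq_len(k)) {
      sp <- stats::mvfft(segt * g[, ki])
      coef[, (ei - 1L) * k + ki, ] <- sp[seq_len(n_keep), , drop = FALSE]
    }
  }
  list(freqs = freqs, coef = coef, n_epochs = length(starts), n_tapers = k,
       fs = fs, nper = nper, channel_names = rownames(data) %||%
         sprintf("ch%02d", seq_len(nch)))
}

# One-sided PSD scaling factors per retained frequency bin.
onesided_factor <- function(freqs, fs, nper) {
  fac <- rep(2, length(freqs))
  fac[freqs == 0] <- 1
  if (nper %% 2 == 0) fac[abs(freqs - fs / 2) < 1e-9] <- 1
  fac
}

csd_from_coef <- function(ce_eeg, ce_err) {
  fac <- onesided_factor(ce_eeg$freqs, ce_eeg$fs, ce_eeg$nper)
  ex <- ce_eeg$coef
  ey <- matrix(ce_err$coef[, , 1], nrow = dim(ce_err$coef)[1])
  s_xx <- apply(abs(ex)^2, c(1, 3), mean) * fac / ce_eeg$fs
  s_yy <- rowMeans(abs(ey)^2) * fac / ce_eeg$fs
  s_xy <- apply(ex * as.vector(Conj(ey)), c(1, 3), mean) * fac / ce_eeg$fs
  structure(list(freqs = ce_eeg$freqs,
                 s_xx = t(s_xx), s_yy = s_yy, s_xy = t(s_xy),
                 n_epochs = ce_eeg$n_epochs, n_tapers = ce_eeg$n_tapers,
                 channel_names = ce_eeg$channel_names),
            class = "spectral_estimate")
}

#' Multitaper auto- and cross-spectral densities
#'
#' Estimates, per EEG channel and per frequency on the `0 - f_max` Hz grid
#' (bin spacing `1/epoch_len_s`, 0.2 Hz for 5 s epochs), the EEG
#' auto-spectral density, the error auto-spectral density, and the complex
#' EEG-error cross-spectral density, pooled over all epochs x tapers.
#'
#' @param eeg A `multichannel_series`, or channels x time matrix (then `fs`
#'   must be given).
#' @param error An [error_series()] or numeric vector at the same rate.
#' @param epoch_len_s,overlap Epoching parameters (5 s epochs, 0.5 overlap).
#' @param n_tapers Number of Slepian tapers (3; realized half-bandwidth
#'   `(n_tapers + 1) / (2 * epoch_len_s)` = 0.4 Hz for the defaults).
#' @param f_max Highest retained frequency, Hz (10).
#' @param taper `"dpss"` (default) or `"hanning"` (single Hann window).
#' @param fs Sampling rate, required when `eeg` is a bare matrix.
#' @return Object of class `spectral_estimate` with fields `freqs`,
#'   `s_xx` (channels x freq), `s_yy` (freq), `s_xy` (channels x freq,
#'   complex), `n_epochs`, `n_tapers`, `channel_names`.
#' @export
mt_csd <- function(eeg, error, epoch_len_s = 5, overlap = 0.5, n_tapers = 3,
                   f_max = 10, taper = "dpss", fs = NULL) {
  fs <- fs %||% (if (inherits(eeg, "multichannel_series")) eeg$fs
                 else if (inherits(error, "error_series")) error$fs
                 else rlang::abort("fs must be supplied for bare-matrix input"))
  err <- if (inherits(error, "error_series")) error$values else as.numeric(error)
  data <- as_signal_matrix(eeg)
  stopifnot_msg(ncol(data) == length(err),
                "EEG and error must have the same number of samples")
  ce_x <- mt_coef(data, fs, epoch_len_s, overlap, n_tapers, f_max, taper)
  ce_y <- mt_coef(matrix(err, nrow = 1), fs, epoch_len_s, overlap, n_tapers,
                  f_max, taper)
  csd_from_coef(ce_x, ce_y)
}

#' Pool spectral estimates across trials
#'
#' Averages auto- and cross-spectral densities across trials (weighted by
#' each trial's number of epoch-taper segments) so that condition-level
#' coherence is formed from the pooled cross-spectral density.
#'
#' @param estimates List of `spectral_estimate` objects on identical
#'   frequency grids.
#' @return A pooled `spectral_estimate`.
#' @export
pool_spectra <- function(estimates) {
  stopifnot_msg(length(estimates) >= 1, "need at least one estimate")
  f0 <- estimates[[1]]$freqs
  for (e in estimates) {
    stopifnot_msg(isTRUE(all.equal(e$freqs, f0)), "frequency grids differ")
  }
  w <- vapply(estimates, function(e) e$n_epochs * e$n_tapers, numeric(1))
  wsum <- sum(w)
  acc <- function(fld) {
    Reduce(`+`, Map(function(e, wi) e[[fld]] * wi, estimates, w)) / wsum
  }
  out <- estimates[[1]]
  out$s_xx <- acc("s_xx"); out$s_yy <- acc("s_yy"); out$s_xy <- acc("s_xy")
  out$n_epochs <- sum(vapply(estimates, `[[`, numeric(1), "n_epochs"))
  out
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("<spectral_estimate> ", nrow(x$s_xx), " ch x ", length(x$freqs),
      " freqs (", min(x$freqs), "-", max(x$freqs), " Hz), ",
      x$n_epochs, " epochs x ", x$n_tapers, " tapers\n", sep = "")
  invisible(x)
}

#' Magnitude coherence spectrum
#'
#' `Coh(f) = |S_xy(f)| / sqrt(S_xx(f) * S_yy(f))`, per channel and
#' frequency, always in `[0, 1]`. Frequencies where either auto-spectrum
#' vanishes are undefined and propagate as `NA` (never as zero); they are
#' excluded from all downstream averages.
#'
#' @param se A `spectral_estimate` (single-trial or pooled).
#' @param kind `"real"` or `"surrogate"` — provenance tag carried on the
#'   result.
#' @param condition Optional condition label.
#' @return A tibble of class `coh_spectrum` with columns `channel`, `freq`
#'   (Hz), `coherence`, and attributes `kind`, `condition`, `n_epochs`,
#'   `n_tapers`.
#' @export
coherence <- function(se, kind = c("real", "surrogate"), condition = NULL) {
  kind <- match.arg(kind)
  stopifnot_msg(inherits(se, "spectral_estimate"), "se must be a spectral_estimate")
  denom <- sweep(se$s_xx, 2, se$s_yy, `*`)
  tol <- 1e-14 * max(denom, 1e-300)
  coh <- abs(se$s_xy) / sqrt(pmax(denom, tol))
  coh[denom <= tol] <- NA_real_
  coh <- pmin(coh, 1)
  out <- tibble::tibble(
    channel = rep(se$channel_names, times = length(se$freqs)),
    freq = rep(se$freqs, each = nrow(se$s_xx)),
    coherence = as.vector(coh)
  )
  new_coh_spectrum(out, kind = kind,
                   condition = condition %||% NA_character_,
                   n_epochs = se$n_epochs, n_tapers = se$n_tapers)
}

new_coh_spectrum <- function(df, kind, condition, n_epochs, n_tapers) {
  structure(df, class = c("coh_spectrum", class(tibble::tibble())),
            kind = kind, condition = condition,
            n_epochs = n_epochs, n_tapers = n_tapers)
}

#' Band-averaged coherence
#'
#' Mean coherence over the frequency bins inside `[f_lo, f_hi]` (inclusive
#' of both edge bins; the default band is the 0-6 Hz range over which
#' neural tracking of movement error is expected), per channel, skipping
#' undefined (`NA`) cells.
#'
#' @param cs A `coh_spectrum`.
#' @param f_lo,f_hi Band edges, Hz.
#' @return Tibble with columns `channel`, `coherence`.
#' @export
band_average <- function(cs, f_lo = 0, f_hi = 6) {
  stopifnot_msg(f_hi >= f_lo, "empty band")
  in_band <- cs$freq >= f_lo - 1e-9 & cs$freq <= f_hi + 1e-9
  stopifnot_msg(any(in_band), "band contains no frequency bins")
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cs)[in_band, ], .data$channel),
    coherence = mean(.data$coherence, na.rm = TRUE), .groups = "drop")
}

#' Coherence normalized by error power
#'
#' Divides coherence by the error auto-spectral density at each frequency,
#' indexing neural tracking per unit of error magnitude (conditions that
#' synchronize better produce smaller errors, which this ratio corrects
#' for). With `f_lo`/`f_hi` given, returns the per-channel band average of
#' the ratio instead.
#'
#' @param cs A `coh_spectrum`.
#' @param se The `spectral_estimate` supplying the error power `s_yy`
#'   (same frequency grid).
#' @param f_lo,f_hi Optional band edges, Hz, for a band-averaged variant.
#' @return Tibble `channel, freq, ratio`, or `channel, ratio` when band
#'   edges are given.
#' @export
coherence_power_ratio <- function(cs, se, f_lo = NULL, f_hi = NULL) {
  stopifnot_msg(isTRUE(all.equal(sort(unique(cs$freq)), se$freqs)),
                "coherence and spectral estimate are on different frequency grids")
  pw <- se$s_yy[match(cs$freq, se$freqs)]
  ratio <- cs$coherence / ifelse(pw > 0, pw, NA_real_)
  out <- tibble::tibble(channel = cs$channel, freq = cs$freq, ratio = ratio)
  if (!is.null(f_lo) && !is.null(f_hi)) {
    in_band <- out$freq >= f_lo - 1e-9 & out$freq <= f_hi + 1e-9
    stopifnot_msg(any(in_band), "band contains no frequency bins")
    out <- dplyr::summarise(dplyr::group_by(out[in_band, ], .data$channel),
                            ratio = mean(.data$ratio, na.rm = TRUE),
                            .groups = "drop")
  }
  out
}

#' Pooled condition-level coherence across trials
#'
#' Computes per-trial multitaper cross-spectra between each trial's EEG and
#' its own error, pools them, and forms the coherence spectrum — the "real"
#' (correctly paired) estimate for one participant and condition.
#'
#' @param trials List of trials; each element needs `$eeg` (channels x time
#'   matrix or `multichannel_series`) and `$error` (vector or
#'   [error_series()]).
#' @param fs Sampling rate, Hz.
#' @param condition Optional label.
#' @param ... Passed to [mt_csd()].
#' @return A `coh_spectrum` (kind `"real"`); the pooled
#'   `spectral_estimate` is attached as attribute `"estimate"`.
#' @export
condition_coherence <- function(trials, fs, condition = NULL, ...) {
  ses <- lapply(trials, function(tr) mt_csd(tr$eeg, tr$error, fs = fs, ...))
  pooled <- pool_spectra(ses)
  out <- coherence(pooled, kind = "real", condition = condition)
  attr(out, "estimate") <- pooled
  out
}
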