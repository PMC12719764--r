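#' Enumerate all derangements of n trials
#'
#' A derangement is a permutation with no fixed point: every EEG trial is
#' paired with a *different* trial's error series, so no genuine alignment
#' leaks into the chance baseline. For 4 trials per condition there are
#' exactly 9 derangements — the exhaustive set of shuffled pairings.
#'
#' @param n Number of trials (>= 2).
#' @return Object of class `permutation_scheme`: list with `n_trials` and
#'   `pairings`, a `subfactorial(n) x n` integer matrix in lexicographic
#'   order; row `r`, column `i` gives the error-trial index paired with EEG
#'   trial `i` under pairing `r`.
#' @export
enumerate_derangements <- function(n) {
  stopifnot_msg(is_scalar_number(n) && n >= 2, "need n >= 2 trials")
  n <- as.integer(n)
  res <- list()
  recurse <- function(prefix, remaining) {
    pos <- length(prefix) + 1L
    if (pos > n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in sort(remaining)) {
      if (v != pos) recurse(c(prefix, v), setdiff(remaining, v))
    }
  }
  recurse(integer(0), seq_len(n))
  pairings <- do.call(rbind, res)
  structure(list(n_trials = n, pairings = pairings),
            class = "permutation_scheme")
}

#' @export
print.permutation_scheme <- function(x, ...) {
  cat("<permutation_scheme> ", nrow(x$pairings), " derangements of ",
      x$n_trials, " trials\n", sep = "")
  invisible(x)
}

# Pooled CSD for one EEG/error trial pairing list, from precomputed
# tapered Fourier coefficients; pairs with unequal epoch counts are
# truncated to the shorter.
paired_csd <- function(coef_eeg, coef_err, eeg_idx, err_idx) {
  ses <- Map(function(i, j) {
    cx <- coef_eeg[[i]]; cy <- coef_err[[j]]
    m_ep <- min(cx$n_epochs, cy$n_epochs)   # truncate to whole epochs
    m <- m_ep * cx$n_tapers
    if (cx$n_epochs > m_ep) { cx$coef <- cx$coef[, seq_len(m), , drop = FALSE]
                              cx$n_epochs <- m_ep }
    if (cy$n_epochs > m_ep) { cy$coef <- cy$coef[, seq_len(m), , drop = FALSE]
                              cy$n_epochs <- m_ep }
    csd_from_coef(cx, cy)
  }, eeg_idx, err_idx)
  pool_spectra(ses)
}

#' Surrogate (trial-shuffled) chance-level coherence
#'
#' For every derangement of the trials within each condition, coherence is
#' computed between each trial's EEG and the *deranged* trial's error, with
#' exactly the same spectral settings as the real pipeline; the resulting
#' spectra are averaged over all pairings and all conditions into a single
#' chance baseline per channel and frequency. Trials of unequal length are
#' reconciled by truncating each cross-pairing to the shorter member's
#' epoch count.
#'
#' @param conditions A named list; each element is a list of trials (each
#'   trial with `$eeg` and `$error`, as in [condition_coherence()]).
#' @param fs Sampling rate, Hz.
#' @param scheme Optional [enumerate_derangements()] result; defaults to
#'   all derangements of the per-condition trial count.
#' @param ... Spectral settings passed to the coefficient computation
#'   (`epoch_len_s`, `overlap`, `n_tapers`, `f_max`, `taper`).
#' @return A `coh_spectrum` (kind `"surrogate"`) — the baseline spectrum
#'   per channel.
#' @export
surrogate_coherence <- function(conditions, fs, scheme = NULL, ...) {
  if (!is.null(conditions$eeg)) conditions <- list(all = list(conditions))
  if (!is.null(conditions[[1]]$eeg)) conditions <- list(all = conditions)
  per_cond <- lapply(conditions, function(trials) {
    stopifnot_msg(length(trials) >= 2, "need >= 2 trials per condition for surrogates")
    sch <- scheme %||% enumerate_derangements(length(trials))
    stopifnot_msg(sch$n_trials == length(trials),
                  "permutation scheme size does not match trial count")
    coef_eeg <- lapply(trials, function(tr) {
      mt_coef(as_signal_matrix(tr$eeg), fs, ...)
    })
    coef_err <- lapply(trials, function(tr) {
      v <- if (inherits(tr$error, "error_series")) tr$error$values else as.numeric(tr$error)
      mt_coef(matrix(v, nrow = 1), fs, ...)
    })
    idx <- seq_along(trials)
    per_pairing <- lapply(seq_len(nrow(sch$pairings)), function(r) {
      se <- paired_csd(coef_eeg, coef_err, idx, sch$pairings[r, ])
      coherence(se, kind = "surrogate")
    })
    per_pairing
  })
  all_spectra <- unlist(per_cond, recursive = FALSE)
  base <- all_spectra[[1]]
  coh_mat <- vapply(all_spectra, function(s) s$coherence,
                    numeric(nrow(base)))
  out <- tibble::tibble(channel = base$channel, freq = base$freq,
                        coherence = rowMeans(coh_mat))
  new_coh_spectrum(out, kind = "surrogate", condition = "baseline",
                   n_epochs = attr(base, "n_epochs"),
                   n_tapers = attr(base, "n_tapers"))
}
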