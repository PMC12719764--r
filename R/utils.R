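#' @importFrom rlang %||% abort warn
#' @importFrom stats fft rnorm sd var cov cor qt median
NULL

# Internal assertion helper: stop with the caller's message if cond is FALSE.
stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Expands one integer seed into independent per-component seeds so that
#' parallel stages (per dyad, per trial, per channel group) consume
#' non-overlapping random streams. The derivation is a fixed integer hash,
#' kept below 2^31 so the result is always a valid R seed.
#'
#' @param seed Master integer seed.
#' @param ... One or more integer or character keys naming the substream
#'   (e.g. `derive_seed(1, "eeg", trial = 3)`).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(paste(k, collapse = ""))) else k <- as.double(k)
    h <- (h * 69069 + k + 1) %% 2147483647
  }
  as.integer(h)
}

# Circular shift of a vector by k samples (positive k delays the signal:
# out[t] = x[t - k], wrapping around).
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

# Band-limited (Fourier) resampling to n_out samples. Exact in-band
# amplitude response; the implicit periodic extension can leak across the
# ends, so callers treat the first/last few samples as a transient.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(real = rep(0, n_out))
  half <- min(ceiling(n / 2), ceiling(n_out / 2)) - 1L  # full positive bins
  Y[1] <- X[1]
  if (half >= 1) {
    k <- seq_len(half)
    Y[1 + k] <- X[1 + k]
    Y[n_out + 1 - k] <- X[n + 1 - k]
  }
  if (n_out < n && n_out %% 2 == 0) {
    Y[1 + n_out / 2] <- Re(X[1 + n_out / 2])       # output Nyquist, real
  } else if (n_out > n && n %% 2 == 0) {
    Y[1 + n / 2] <- X[1 + n / 2] / 2               # split input Nyquist
    Y[n_out + 1 - n / 2] <- X[1 + n / 2] / 2
  }
  Re(fft(Y, inverse = TRUE)) / n
}
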