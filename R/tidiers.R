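# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a coherence spectrum
#'
#' @param x A `coh_spectrum`.
#' @param ... Unused.
#' @return Tibble `channel, freq, coherence, kind, condition`.
#' @export
tidy.coh_spectrum <- function(x, ...) {
  tibble::tibble(channel = x$channel, freq = x$freq,
                 coherence = x$coherence,
                 kind = attr(x, "kind"),
                 condition = attr(x, "condition"))
}

#' One-row summary of a coherence spectrum
#'
#' @param x A `coh_spectrum`.
#' @param f_lo,f_hi Band for the summary average, Hz.
#' @param ... Unused.
#' @return Tibble with the grand band average and estimator bookkeeping.
#' @export
glance.coh_spectrum <- function(x, f_lo = 0, f_hi = 6, ...) {
  ba <- band_average(x, f_lo, f_hi)
  tibble::tibble(kind = attr(x, "kind"),
                 condition = attr(x, "condition"),
                 n_channels = length(unique(x$channel)),
                 n_freqs = length(unique(x$freq)),
                 n_epochs = attr(x, "n_epochs"),
                 n_tapers = attr(x, "n_tapers"),
                 band_lo = f_lo, band_hi = f_hi,
                 mean_band_coherence = mean(ba$coherence, na.rm = TRUE))
}

#' @export
autoplot.coh_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$freq, y = .data$coherence,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Coherence",
                  colour = "Channel",
                  title = paste0("EEG-error coherence (", attr(object, "kind"), ")")) +
    ggplot2::theme_minimal()
}

#' Tidy a lag profile
#'
#' @param x A `lag_profile`.
#' @param ... Unused.
#' @return Tibble `group, lag, coherence`.
#' @export
tidy.lag_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Peak summary of a lag profile
#'
#' @param x A `lag_profile`.
#' @param ... Unused.
#' @return Tibble `group, peak_coh, peak_lag` (one row per group).
#' @export
glance.lag_profile <- function(x, ...) {
  peaks(x)
}

#' @export
autoplot.lag_profile <- function(object, ...) {
  pk <- peaks(object)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$lag, y = .data$coherence,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = pk,
                        ggplot2::aes(xintercept = .data$peak_lag,
                                     colour = .data$group),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = "Error time lag (s)",
                  y = sprintf("Coherence (%g-%g Hz)",
                              attr(object, "band")[1], attr(object, "band")[2]),
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Tidy a cluster test result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble of clusters: `freq_lo, freq_hi, mass, p_value`.
#' @export
tidy.cluster_result <- function(x, ...) {
  x$clusters
}

#' One-row summary of a cluster test
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble with cluster counts, threshold, and the smallest p.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(type = x$type,
                 n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$p_value <= x$alpha),
                 threshold = x$threshold,
                 n_permutations = x$n_permutations,
                 min_p = if (nrow(x$clusters)) min(x$clusters$p_value) else NA_real_)
}

#' @export
autoplot.cluster_result <- function(object, ...) {
  sig <- object$clusters[object$clusters$p_value <= object$alpha, , drop = FALSE]
  p <- ggplot2::ggplot(object$stat_series,
                       ggplot2::aes(x = .data$freq, y = .data$stat)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Statistic",
                  title = "Point-wise statistic with significant clusters") +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_rect(
      data = sig, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$freq_lo, xmax = .data$freq_hi,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.15)
  }
  p
}

#' @importFrom rlang .data
NULL
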