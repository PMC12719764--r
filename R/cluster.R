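# Frequency-axis cluster-based permutation statistics.
#
# Point-wise statistics (paired t or Pearson correlation) are computed at
# every frequency; contiguous runs of supra-threshold frequencies form
# clusters whose mass is the sum of |statistic|; the family-wise null is
# the distribution of the maximum cluster mass over sign-flip (t-test) or
# subject-shuffle (correlation) permutations. Adjacency is 1-D along the
# frequency axis only, matching use on channel-averaged spectra.

#' Point-wise paired t statistics
#'
#' Paired t statistic per frequency for subjects x frequency matrices `a`
#' and `b`; rows with a missing value at a frequency are dropped pairwise
#' at that frequency. A zero-variance difference with nonzero mean yields
#' `Inf` (treated as supra-threshold in cluster formation); with zero mean
#' it yields 0.
#'
#' @param a,b Numeric matrices, subjects x frequencies.
#' @return Numeric vector of t statistics, one per frequency.
#' @export
pointwise_paired_t <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot_msg(all(dim(a) == dim(b)), "a and b must have identical dimensions")
  stopifnot_msg(nrow(a) >= 3, "need at least 3 paired subjects")
  d <- a - b
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[is.finite(x)]
    if (length(x) < 3) return(NA_real_)
    m <- mean(x); s <- sd(x)
    if (s < .Machine$double.eps) {
      if (abs(m) < .Machine$double.eps) 0 else sign(m) * Inf
    } else m / (s / sqrt(length(x)))
  }, numeric(1))
}

#' Point-wise Pearson correlations with t statistics
#'
#' Pearson correlation per frequency between subject vectors of `x` and
#' `y`, with the corresponding t statistic `r * sqrt((n-2)/(1-r^2))` used
#' for cluster thresholding. A constant column is undefined and treated as
#' sub-threshold (statistic 0, correlation `NA`).
#'
#' @param x,y Numeric matrices, subjects x frequencies.
#' @return List with `r` and `t`, each one value per frequency.
#' @export
pointwise_correlation <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot_msg(all(dim(x) == dim(y)), "x and y must have identical dimensions")
  stopifnot_msg(nrow(x) >= 4, "need at least 4 subjects")
  r <- vapply(seq_len(ncol(x)), function(j) {
    ok <- is.finite(x[, j]) & is.finite(y[, j])
    if (sum(ok) < 4) return(NA_real_)
    if (sd(x[ok, j]) < .Machine$double.eps || sd(y[ok, j]) < .Machine$double.eps)
      return(NA_real_)
    cor(x[ok, j], y[ok, j])
  }, numeric(1))
  n <- colSums(is.finite(x) & is.finite(y))
  t <- ifelse(is.na(r), 0, r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, 1e-300)))
  list(r = r, t = t)
}

# Maximum cluster mass of |stat| runs above threshold (0 if none).
max_cluster_mass <- function(stat, threshold) {
  supra <- is.finite(stat) & abs(stat) > threshold
  supra[is.infinite(stat)] <- TRUE
  if (!any(supra)) return(0)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- abs(stat)
  max(vapply(which(r$values), function(i) {
    seg <- vals[starts[i]:ends[i]]
    sum(pmin(seg, .Machine$double.xmax))  # Inf capped so mass stays ordered
  }, numeric(1)))
}

cluster_table <- function(stat, threshold, freqs) {
  supra <- (is.finite(stat) & abs(stat) > threshold) | is.infinite(stat)
  if (!any(supra)) {
    return(tibble::tibble(freq_lo = numeric(0), freq_hi = numeric(0),
                          mass = numeric(0)))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble::tibble(
    freq_lo = freqs[starts[keep]],
    freq_hi = freqs[ends[keep]],
    mass = vapply(keep, function(i)
      sum(pmin(abs(stat[starts[i]:ends[i]]), .Machine$double.xmax)),
      numeric(1)))
}

#' Cluster-based permutation test along the frequency axis
#'
#' Forms clusters of adjacent frequencies whose point-wise statistic
#' exceeds the two-sided parametric critical value at `alpha`, measures
#' each cluster's mass as the sum of absolute statistics, and compares the
#' masses against the permutation distribution of the *maximum* cluster
#' mass: random sign flips of the paired differences for `type =
#' "paired_t"`, or subject-label shuffles of `b` for `type =
#' "correlation"` (sign flips are undefined for correlations). Permutation
#' datasets with no supra-threshold cluster contribute a maximum mass of
#' zero. P-values use the add-one convention `(b + 1) / (m + 1)` by
#' default, so they are never exactly zero; the raw-proportion variant is
#' available via `p_convention = "raw"`.
#'
#' @param a,b Subjects x frequencies matrices: the paired conditions
#'   (`paired_t`) or the two correlated variables (`correlation`).
#' @param freqs Frequency grid, Hz (defaults to bin indices).
#' @param type `"paired_t"` or `"correlation"`.
#' @param n_perm Number of random permutations (default 1000).
#' @param alpha Two-sided alpha for the cluster-defining threshold.
#' @param seed Integer seed for the permutation draws.
#' @param p_convention `"add_one"` (default) or `"raw"`.
#' @return Object of class `cluster_result`: list with `clusters` (tibble
#'   `freq_lo, freq_hi, mass, p_value`), `stat_series` (tibble `freq,
#'   stat`), `threshold`, `n_permutations`, `null_max` (the permutation
#'   distribution), `alpha`, `type`.
#' @export
cluster_permutation <- function(a, b, freqs = NULL,
                                type = c("paired_t", "correlation"),
                                n_perm = 1000, alpha = 0.05, seed = 1L,
                                p_convention = c("add_one", "raw")) {
  type <- match.arg(type)
  p_convention <- match.arg(p_convention)
  stopifnot_msg(n_perm >= 1, "n_perm must be >= 1")
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); nf <- ncol(a)
  freqs <- freqs %||% seq_len(nf)
  stopifnot_msg(length(freqs) == nf, "freqs length must match column count")

  if (type == "paired_t") {
    stat <- pointwise_paired_t(a, b)
    threshold <- qt(1 - alpha / 2, df = n - 1)
  } else {
    pc <- pointwise_correlation(a, b)
    stat <- pc$t
    threshold <- qt(1 - alpha / 2, df = n - 2)
  }

  set.seed(as.integer(seed))
  if (type == "paired_t") {
    d <- a - b
    q <- colSums(d^2)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm)
    ms <- signs %*% d / n
    vars <- sweep(-n * ms^2, 2, q, `+`) / (n - 1)
    tmat <- ms / sqrt(pmax(vars, 0) / n)
    tmat[!is.finite(tmat)] <- 0
    null_max <- vapply(seq_len(n_perm), function(i)
      max_cluster_mass(tmat[i, ], threshold), numeric(1))
  } else {
    null_max <- vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(n)
      stat_p <- pointwise_correlation(a, b[perm, , drop = FALSE])$t
      max_cluster_mass(stat_p, threshold)
    }, numeric(1))
  }

  cl <- cluster_table(stat, threshold, freqs)
  if (nrow(cl) > 0) {
    cl$p_value <- vapply(cl$mass, function(m0) {
      # tolerance so exact ties survive the two arithmetic paths
      bcount <- sum(null_max >= m0 - 1e-8 * max(m0, 1))
      if (p_convention == "add_one") (bcount + 1) / (n_perm + 1)
      else bcount / n_perm
    }, numeric(1))
  } else {
    cl$p_value <- numeric(0)
  }

  structure(list(
    clusters = cl,
    stat_series = tibble::tibble(freq = freqs, stat = stat),
    threshold = threshold, n_permutations = n_perm,
    null_max = null_max, alpha = alpha, type = type
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", x$type, ", threshold |t| > ",
      signif(x$threshold, 4), ", ", x$n_permutations, " permutations\n",
      sep = "")
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(x$clusters)
  }
  invisible(x)
}
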