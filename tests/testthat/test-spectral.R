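test_that("epoching follows the 5 s / 50% overlap truncation rules", {
  expect_length(epoch_starts(180 * 500, 500), 71)
  expect_length(epoch_starts(5 * 500, 500), 1)
  expect_length(epoch_starts(round(7.4 * 500), 500), 1)
  expect_length(epoch_starts(round(7.5 * 500), 500), 2)
  expect_error(epoch_starts(1000, 500), "shorter")
  ep <- epoch_signal(rnorm(3000), fs = 200, epoch_len_s = 5, overlap = 0.5)
  expect_equal(dim(ep), c(1000, 5))   # 15 s -> starts at 0, 2.5, ..., 10 s
  expect_equal(ep[501:1000, 1], ep[1:500, 2])   # 50% overlap shares halves
})

test_that("a single epoch-taper cross-spectrum is rank one", {
  set.seed(7)
  x <- matrix(rnorm(500), 1)
  y <- rnorm(500)
  se <- mt_csd(x, y, fs = 100, n_tapers = 1, f_max = 50)
  expect_equal(Mod(se$s_xy[1, ])^2, se$s_xx[1, ] * se$s_yy,
               tolerance = 1e-10)
})

test_that("auto-spectra satisfy Parseval and peak at the tone frequency", {
  fs <- 100
  t_ax <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1 * t_ax)
  se <- mt_csd(matrix(x, 1), x, fs = fs, n_tapers = 3, f_max = fs / 2)
  expect_equal(se$freqs[which.max(se$s_xx[1, ])], 1)
  # Parseval: integral of the PSD equals the mean tapered-epoch energy
  tapers <- dpss_tapers(length(x), nw = 2, k = 3)
  xd <- x - mean(x)
  energy <- mean(colSums((xd * tapers)^2))
  df <- se$freqs[2] - se$freqs[1]
  expect_equal(sum(se$s_xx[1, ]) * df, energy, tolerance = 1e-10)
})

test_that("coherence is 1 for identical signals and invariant to scaling", {
  set.seed(21)
  y <- rnorm(4000)
  x <- rbind(y, rnorm(4000))
  se <- mt_csd(x, y, fs = 100, f_max = 10)
  cs <- coherence(se)
  c1 <- cs$coherence[cs$channel == "ch01"]
  expect_true(all(abs(c1 - 1) < 1e-10))
  # positive rescaling of channel or error leaves coherence untouched
  se2 <- mt_csd(x * 37.5, y * 0.004, fs = 100, f_max = 10)
  expect_equal(coherence(se2)$coherence, cs$coherence, tolerance = 1e-12)
  # Cauchy-Schwarz bound, strict for pooled independent signals
  c2 <- cs$coherence[cs$channel == "ch02"]
  expect_true(all(c2 <= 1))
  expect_true(all(c2 < 1))
})

test_that("pooled null coherence matches the independent-signal expectation", {
  # two independent Gaussian signals: E|coh| ~ sqrt(pi / (4 N)) for N
  # pooled segment-tapers; Monte-Carlo mean must sit within 2 SE
  set.seed(31)
  n_rep <- 60
  fs <- 50
  n <- fs * 50   # 10 non-overlapping 5 s epochs x 3 tapers = 30 segment-tapers
  means <- vapply(seq_len(n_rep), function(i) {
    se <- mt_csd(matrix(rnorm(n), 1), rnorm(n), fs = fs, overlap = 0,
                 f_max = 10)
    cs <- coherence(se)
    mean(cs$coherence[cs$freq > 0], na.rm = TRUE)
  }, numeric(1))
  n_seg <- 10 * 3
  expected <- sqrt(pi / (4 * n_seg))
  se_mc <- sd(means) / sqrt(n_rep)
  expect_lt(abs(mean(means) - expected), max(2 * se_mc, 0.1 * expected))
})

test_that("coherence of signal-plus-noise follows the SNR law", {
  # channel = error + background with flat per-frequency SNR = 1:
  # coherence -> sqrt(snr / (1 + snr)) = sqrt(0.5)
  set.seed(33)
  fs <- 100
  n <- fs * 200
  err <- rnorm(n)
  ch <- err + rnorm(n)
  se <- mt_csd(matrix(ch, 1), err, fs = fs, f_max = 10)
  ba <- band_average(coherence(se), 0, 10)
  expect_lt(abs(ba$coherence - sqrt(0.5)), 0.05)
})

test_that("band averaging and the coherence-power ratio reduce correctly", {
  freqs <- seq(0, 10, by = 0.2)
  nf <- length(freqs)
  set.seed(41)
  coh_vals <- runif(2 * nf)
  cs <- dyadcoh:::new_coh_spectrum(
    tibble::tibble(channel = rep(c("ch01", "ch02"), times = nf),
                   freq = rep(freqs, each = 2), coherence = coh_vals),
    kind = "real", condition = NA_character_, n_epochs = 10, n_tapers = 3)
  ba <- band_average(cs, 0, 6)
  for (chn in c("ch01", "ch02")) {
    direct <- mean(coh_vals[rep(c("ch01", "ch02"), times = nf) == chn &
                              rep(freqs, each = 2) <= 6])
    expect_equal(ba$coherence[ba$channel == chn], direct, tolerance = 1e-14)
  }
  # constant and linear-in-frequency spectra
  cs_const <- dyadcoh:::new_coh_spectrum(
    tibble::tibble(channel = "ch01", freq = freqs, coherence = 0.37),
    kind = "real", condition = NA_character_, n_epochs = 1, n_tapers = 1)
  expect_equal(band_average(cs_const, 0, 6)$coherence, 0.37)
  cs_lin <- dyadcoh:::new_coh_spectrum(
    tibble::tibble(channel = "ch01", freq = freqs, coherence = 0.1 * freqs),
    kind = "real", condition = NA_character_, n_epochs = 1, n_tapers = 1)
  expect_equal(band_average(cs_lin, 0, 6)$coherence, 0.1 * 3)

  # ratio: element-wise division against a direct oracle, and the
  # amplitude-scaling law (coherence unchanged, error power x4 => ratio /4)
  set.seed(43)
  y <- rnorm(3000)
  x <- matrix(y + rnorm(3000), 1)
  se <- mt_csd(x, y, fs = 100, f_max = 10)
  cs2 <- coherence(se)
  rat <- coherence_power_ratio(cs2, se)
  expect_equal(rat$ratio, cs2$coherence / se$s_yy[match(cs2$freq, se$freqs)],
               tolerance = 1e-14)
  se_big <- mt_csd(x, 2 * y, fs = 100, f_max = 10)
  rat_big <- coherence_power_ratio(coherence(se_big), se_big)
  expect_equal(rat_big$ratio, rat$ratio / 4, tolerance = 1e-10)
})

test_that("undefined cells propagate as missing, not zero", {
  x <- matrix(0, 1, 1000)        # silent channel: all auto-power zero
  y <- rnorm(1000)
  se <- mt_csd(x, y, fs = 100, f_max = 10)
  cs <- coherence(se)
  expect_true(all(is.na(cs$coherence)))
  expect_true(is.nan(band_average(cs, 0, 6)$coherence))
})

test_that("band coherence rises monotonically with tracking SNR", {
  snrs <- c(0, 0.25, 1, 4)
  vals <- vapply(snrs, function(s) {
    cfg <- quick_cfg(duration_s = 40, tracking_snr = s, seed = 77L)
    tr <- simulate_dyad_trial(cfg)
    cs <- condition_coherence(list(pair_of(tr)), fs = cfg$fs_eeg)
    ba <- band_average(cs)
    ba$coherence[ba$channel == "ch01"]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("follower configured with higher SNR out-coheres leader", {
  mk <- function(cond, snr) {
    cfg <- quick_cfg(duration_s = 40, condition = cond, tracking_snr = snr,
                     seed = 99L)
    tr <- simulate_dyad_trial(cfg)
    cs <- condition_coherence(list(pair_of(tr)), fs = cfg$fs_eeg)
    mean(band_average(cs)$coherence[1])
  }
  expect_gt(mk("follower", 2), mk("leader", 0.5))
})
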