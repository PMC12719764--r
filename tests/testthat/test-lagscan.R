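test_that("the lag grid has the canonical size and closed forms", {
  expect_length(lag_grid(-2, 2, 0.02), 201)
  expect_equal(lag_grid(0, 0, 0.5), 0)
  expect_equal(lag_grid(-1, 1, 0.5), c(-1, -0.5, 0, 0.5, 1))
  g <- lag_grid()
  expect_true(0 %in% g)
  expect_equal(g, -rev(g))                      # symmetric around zero
  expect_equal(diff(g), rep(0.02, 200), tolerance = 1e-12)
  expect_error(lag_grid(-1, 1, 0.3), "multiples")
})

test_that("a constructed shift is recovered exactly with coherence 1", {
  fs <- 100
  err <- lowpass_noise(60 * fs, fs, 4, seed = 61)^2   # nonnegative-ish error
  shift <- round(0.10 * fs)
  eeg <- matrix(c(rep(0, shift), err[1:(length(err) - shift)]), 1,
                dimnames = list("ch01", NULL))  # eeg(t) = err(t - 0.10 s)
  prof <- lagged_coherence(list(eeg = eeg, error = err), fs = fs,
                           lags = lag_grid(-0.5, 0.5, 0.02))
  pk <- peaks(prof)
  expect_equal(pk$peak_lag, 0.10)
  expect_equal(pk$peak_coh, 1, tolerance = 1e-9)
})

test_that("shifting the error shifts the whole profile (grid quantization)", {
  fs <- 100
  err <- lowpass_noise(120 * fs, fs, 4, seed = 63)^2
  eeg <- matrix(err - mean(err), 1, dimnames = list("ch01", NULL))
  # delay the error by delta: eeg then leads it, the profile moves -delta
  delta <- 0.1
  err_shifted <- c(rep(err[1], delta * fs), err[1:(length(err) - delta * fs)])
  lags <- lag_grid(-0.4, 0.4, 0.02)
  p0 <- lagged_coherence(list(eeg = eeg, error = err), fs = fs, lags = lags)
  p1 <- lagged_coherence(list(eeg = eeg, error = err_shifted), fs = fs,
                         lags = lags)
  expect_equal(peaks(p1)$peak_lag, peaks(p0)$peak_lag - delta,
               tolerance = 1e-9)
  # interior profile values line up after shifting the lag axis
  joined <- merge(tidy(p0), transform(tidy(p1), lag = lag + delta),
                  by = c("group", "lag"))
  expect_gt(nrow(joined), 20)
  expect_lt(max(abs(joined$coherence.x - joined$coherence.y)), 0.03)
})

test_that("stored profiles reproduce their own peaks and group averages", {
  fs <- 100
  cfg <- quick_cfg(duration_s = 40, n_channels = 3, n_tracking_channels = 2,
                   fs_eeg = fs)
  tr <- simulate_dyad_trial(cfg)
  prof <- lagged_coherence(pair_of(tr), fs = fs,
                           lags = lag_grid(-0.3, 0.3, 0.02))
  pk <- peaks(prof)
  for (g in pk$group) {
    sub <- tidy(prof)[tidy(prof)$group == g, ]
    expect_equal(pk$peak_coh[pk$group == g], max(sub$coherence))
    expect_true(pk$peak_lag[pk$group == g] %in% sub$lag)
  }
  # single-channel group is the identity; two-channel group is the mean
  g1 <- group_average(prof, list(solo = "ch01"))
  expect_equal(g1$coherence, prof$coherence[prof$group == "ch01"],
               tolerance = 1e-14)
  g2 <- group_average(prof, list(track = c("ch01", "ch02")))
  direct <- (prof$coherence[prof$group == "ch01"] +
               prof$coherence[prof$group == "ch02"]) / 2
  expect_equal(g2$coherence, direct, tolerance = 1e-14)
  expect_error(group_average(prof, list(bad = character(0))), "empty")
  expect_error(group_average(prof, list(bad = "ch99")), "unknown")
})

test_that("peak ties break toward the smallest absolute lag, negative first", {
  mk_prof <- function(lags, coh) {
    dyadcoh:::new_lag_profile(
      tibble::tibble(group = "g", lag = lags, coherence = coh),
      fs = 100, band = c(0, 6))
  }
  expect_equal(peaks(mk_prof(c(-0.2, 0, 0.2), c(0.5, 0.2, 0.5)))$peak_lag, -0.2)
  expect_equal(peaks(mk_prof(c(-0.1, 0.1), c(0.4, 0.4)))$peak_lag, -0.1)
  expect_equal(peaks(mk_prof(c(-0.3, 0.1), c(0.4, 0.4)))$peak_lag, 0.1)
})

test_that("the movement control behaves at its identity and degenerate limits", {
  fs <- 100
  err <- lowpass_noise(50 * fs, fs, 3, seed = 67)^2
  # control equal to the error itself: perfect coherence at zero lag
  prof_id <- movement_control_lagscan(err, err, fs = fs,
                                      lags = lag_grid(-0.2, 0.2, 0.02))
  pk <- peaks(prof_id)
  expect_equal(pk$peak_lag, 0)
  expect_equal(pk$peak_coh, 1, tolerance = 1e-9)
  # near-constant control: coherence undefined, flagged as missing
  flat <- rep(0, 50 * fs)
  prof_flat <- movement_control_lagscan(flat, err, fs = fs,
                                        lags = lag_grid(-0.1, 0.1, 0.02))
  expect_true(all(is.na(prof_flat$coherence) | is.nan(prof_flat$coherence)))
})

test_that("ground-truth tracking lags are recovered from simulated dyads", {
  fs <- 100
  for (lag_true in c(-0.1, 0.1)) {
    errs <- vapply(1:3, function(s) {
      cfg <- quick_cfg(duration_s = 50, fs_eeg = fs, tracking_snr = 2,
                       tracking_lag_s = lag_true, n_channels = 1,
                       n_tracking_channels = 1, seed = 300L + s)
      tr <- simulate_dyad_trial(cfg)
      prof <- lagged_coherence(pair_of(tr), fs = fs,
                               lags = lag_grid(-0.5, 0.5, 0.02))
      abs(peaks(prof)$peak_lag - lag_true)
    }, numeric(1))
    expect_lte(median(errs), 0.04)
  }
})
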