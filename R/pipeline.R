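# End-to-end orchestration: simulate -> kinematics -> coherence ->
# surrogates -> lag scan -> cluster statistics, with a config echo and a
# manifest so every number is traceable to a configuration and seed.

#' Pipeline run configuration
#'
#' Bundles the generator, spectral, lag-scan, and statistics settings for
#' one reproducible end-to-end run. Per-condition tracking parameters
#' default to the qualitative structure expected of leadership roles:
#' followers track the error more strongly and with a longer (more
#' positive) latency than leaders, with the joint condition in between.
#'
#' @param n_dyads Number of simulated dyads (each contributes two
#'   participants).
#' @param n_trials Trials per condition (4).
#' @param conditions Conditions to simulate.
#' @param duration_s,fs_motion,fs_eeg,base_freq,drift_std,coupling_strength,follower_delay_s,n_channels,n_tracking_channels,noise_std,noise_exponent
#'   Passed to [dyad_config()].
#' @param condition_snr,condition_lag_s Named numeric vectors giving each
#'   condition's tracking signal-to-noise ratio and tracking lag (s).
#' @param epoch_len_s,overlap,n_tapers,f_max Spectral settings.
#' @param band Two-element analysis band, Hz.
#' @param lag_min,lag_max,lag_step Lag-scan grid, seconds.
#' @param n_perm,alpha Cluster-permutation settings.
#' @param seed Master seed; all stages derive substreams from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_dyads = 8, n_trials = 4,
                       conditions = c("follower", "leader", "joint"),
                       duration_s = 180, fs_motion = 240, fs_eeg = 500,
                       base_freq = 1, drift_std = 0.05,
                       coupling_strength = 0.8, follower_delay_s = 0.2,
                       condition_snr = c(follower = 2, leader = 0.5, joint = 1),
                       condition_lag_s = c(follower = 0.2, leader = 0.04,
                                           joint = 0.1),
                       n_channels = 8, n_tracking_channels = 2,
                       noise_std = 0.01, noise_exponent = 1,
                       epoch_len_s = 5, overlap = 0.5, n_tapers = 3,
                       f_max = 10, band = c(0, 6),
                       lag_min = -2, lag_max = 2, lag_step = 0.02,
                       n_perm = 1000, alpha = 0.05, seed = 1L) {
  stopifnot_msg(n_dyads >= 1 && n_trials >= 2,
                "need >= 1 dyad and >= 2 trials per condition")
  stopifnot_msg(all(conditions %in% names(condition_snr)) &&
                  all(conditions %in% names(condition_lag_s)),
                "condition_snr and condition_lag_s must name every condition")
  # validate every stage's settings before any stage runs
  invisible(lag_grid(lag_min, lag_max, lag_step))
  stopifnot_msg(band[1] < band[2] && band[2] <= f_max, "invalid analysis band")
  stopifnot_msg(n_perm >= 1 && alpha > 0 && alpha < 1, "invalid stats settings")
  invisible(dyad_config(duration_s = duration_s, fs_motion = fs_motion,
                        fs_eeg = fs_eeg, condition = conditions[1],
                        base_freq = base_freq, drift_std = drift_std,
                        coupling_strength = coupling_strength,
                        follower_delay_s = follower_delay_s,
                        n_channels = n_channels,
                        n_tracking_channels = n_tracking_channels,
                        noise_std = noise_std, noise_exponent = noise_exponent,
                        seed = seed))
  structure(as.list(environment()), class = "run_config")
}

trial_pairs <- function(trials, side) {
  lapply(trials, function(tr) {
    list(eeg = if (side == "a") tr$eeg_a else tr$eeg_b, error = tr$error)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates `n_dyads` dyads (two participants each) across the requested
#' conditions, computes per-participant condition-level EEG-error
#' coherence, the derangement surrogate baseline, band averages and
#' coherence/error-power ratios, the lag scan with tracking/background
#' channel groups, and the cluster-permutation statistics (real vs
#' surrogate coherence; error power designated vs undesignated leadership;
#' coherence-error-magnitude correlation). All final tables are written as
#' CSV, the cluster report as JSON, the configuration echo as YAML, and a
#' manifest with seeds and file checksums as JSON.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param stages Character subset of
#'   `c("simulate", "coherence", "lagscan", "stats")`. Later stages need
#'   the simulated trials: requesting them without `"simulate"` is refused
#'   unless a previous run wrote raw trials into `out_dir/trials`.
#' @param write_raw Also write every simulated trial as a plain-text
#'   container (large; off by default).
#' @return Invisibly, a list with the in-memory results (`coherence`,
#'   `band`, `ratio`, `error_power`, `peaks`, `profiles`, `clusters`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "coherence", "lagscan", "stats"),
                         write_raw = FALSE) {
  stopifnot_msg(inherits(config, "run_config"), "config must be a run_config")
  stages <- match.arg(stages, c("simulate", "coherence", "lagscan", "stats"),
                      several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_list <- unclass(config)
  yaml::write_yaml(cfg_list, file.path(out_dir, "config.yaml"))

  trials_by <- NULL   # trials_by[[dyad]][[condition]] = list of dyad_trial
  if ("simulate" %in% stages) {
    trials_by <- lapply(seq_len(config$n_dyads), function(d) {
      per_cond <- lapply(config$conditions, function(cond) {
        cfg <- dyad_config(
          duration_s = config$duration_s, fs_motion = config$fs_motion,
          fs_eeg = config$fs_eeg, condition = cond,
          base_freq = config$base_freq, drift_std = config$drift_std,
          coupling_strength = config$coupling_strength,
          follower_delay_s = config$follower_delay_s,
          tracking_lag_s = config$condition_lag_s[[cond]],
          tracking_snr = config$condition_snr[[cond]],
          n_channels = config$n_channels,
          n_tracking_channels = config$n_tracking_channels,
          noise_std = config$noise_std,
          noise_exponent = config$noise_exponent,
          seed = derive_seed(config$seed, "dyad", d, cond))
        simulate_condition_trials(cfg, config$n_trials)
      })
      names(per_cond) <- config$conditions
      per_cond
    })
    if (write_raw) {
      for (d in seq_along(trials_by)) {
        for (cond in names(trials_by[[d]])) {
          for (k in seq_along(trials_by[[d]][[cond]])) {
            write_trial(trials_by[[d]][[cond]][[k]],
                        file.path(out_dir, "trials",
                                  sprintf("dyad%02d", d), cond,
                                  sprintf("trial%d", k)))
          }
        }
      }
    }
  } else {
    tdir <- file.path(out_dir, "trials")
    if (!dir.exists(tdir)) {
      rlang::abort(paste0(
        "stage '", setdiff(stages, "simulate")[1], "' needs simulated trials, ",
        "but none were found in ", tdir,
        ". Run the pipeline with the 'simulate' stage first (or with ",
        "write_raw = TRUE to persist trials for resumed runs)."))
    }
    trials_by <- lapply(list.dirs(tdir, recursive = FALSE), function(dd) {
      per_cond <- lapply(list.dirs(dd, recursive = FALSE), function(cd) {
        lapply(list.dirs(cd, recursive = FALSE), read_trial)
      })
      names(per_cond) <- basename(list.dirs(dd, recursive = FALSE))
      per_cond
    })
  }

  spectral_args <- list(epoch_len_s = config$epoch_len_s,
                        overlap = config$overlap, n_tapers = config$n_tapers,
                        f_max = config$f_max)
  participants <- expand.grid(dyad = seq_along(trials_by), side = c("a", "b"),
                              stringsAsFactors = FALSE)
  results <- list()

  if (any(c("coherence", "lagscan", "stats") %in% stages)) {
    coh_rows <- list(); pow_rows <- list(); band_rows <- list(); ratio_rows <- list()
    for (p in seq_len(nrow(participants))) {
      d <- participants$dyad[p]; side <- participants$side[p]
      pid <- sprintf("d%02d%s", d, side)
      conds <- lapply(trials_by[[d]], trial_pairs, side = side)
      for (cond in names(conds)) {
        cs <- do.call(condition_coherence,
                      c(list(conds[[cond]], fs = config$fs_eeg,
                             condition = cond), spectral_args))
        se <- attr(cs, "estimate")
        coh_rows[[length(coh_rows) + 1L]] <-
          dplyr::mutate(tidy(cs), participant = pid)
        pow_rows[[length(pow_rows) + 1L]] <-
          tibble::tibble(participant = pid, condition = cond,
                         freq = se$freqs, power = se$s_yy)
        ba <- band_average(cs, config$band[1], config$band[2])
        band_rows[[length(band_rows) + 1L]] <-
          dplyr::mutate(ba, participant = pid, condition = cond,
                        kind = "real")
        rr <- coherence_power_ratio(cs, se, config$band[1], config$band[2])
        ratio_rows[[length(ratio_rows) + 1L]] <-
          dplyr::mutate(rr, participant = pid, condition = cond)
      }
      base <- do.call(surrogate_coherence,
                      c(list(conds, fs = config$fs_eeg), spectral_args))
      coh_rows[[length(coh_rows) + 1L]] <-
        dplyr::mutate(tidy(base), participant = pid)
      band_rows[[length(band_rows) + 1L]] <-
        dplyr::mutate(band_average(base, config$band[1], config$band[2]),
                      participant = pid, condition = "baseline",
                      kind = "surrogate")
    }
    results$coherence <- dplyr::bind_rows(coh_rows)
    results$error_power <- dplyr::bind_rows(pow_rows)
    results$band <- dplyr::bind_rows(band_rows)
    results$ratio <- dplyr::bind_rows(ratio_rows)
    utils::write.csv(results$coherence,
                     file.path(out_dir, "coherence_long.csv"), row.names = FALSE)
    utils::write.csv(results$error_power,
                     file.path(out_dir, "error_power.csv"), row.names = FALSE)
    utils::write.csv(results$band,
                     file.path(out_dir, "band_average.csv"), row.names = FALSE)
    utils::write.csv(results$ratio,
                     file.path(out_dir, "coherence_power_ratio.csv"),
                     row.names = FALSE)
  }

  if ("lagscan" %in% stages) {
    lags <- lag_grid(config$lag_min, config$lag_max, config$lag_step)
    groups <- list(
      tracking = sprintf("ch%02d", seq_len(config$n_tracking_channels)))
    if (config$n_channels > config$n_tracking_channels) {
      groups$background <- sprintf(
        "ch%02d", seq(config$n_tracking_channels + 1, config$n_channels))
    }
    prof_rows <- list(); peak_rows <- list()
    for (p in seq_len(nrow(participants))) {
      d <- participants$dyad[p]; side <- participants$side[p]
      pid <- sprintf("d%02d%s", d, side)
      for (cond in names(trials_by[[d]])) {
        prof <- lagged_coherence(trial_pairs(trials_by[[d]][[cond]], side),
                                 fs = config$fs_eeg, lags = lags,
                                 band = config$band,
                                 epoch_len_s = config$epoch_len_s,
                                 overlap = config$overlap,
                                 n_tapers = config$n_tapers)
        gprof <- group_average(prof, groups)
        prof_rows[[length(prof_rows) + 1L]] <-
          dplyr::mutate(tidy(gprof), participant = pid, condition = cond)
        peak_rows[[length(peak_rows) + 1L]] <-
          dplyr::mutate(peaks(gprof), participant = pid, condition = cond)
      }
    }
    results$profiles <- dplyr::bind_rows(prof_rows)
    results$peaks <- dplyr::bind_rows(peak_rows)
    utils::write.csv(results$profiles,
                     file.path(out_dir, "lag_profiles.csv"), row.names = FALSE)
    utils::write.csv(results$peaks,
                     file.path(out_dir, "lag_peaks.csv"), row.names = FALSE)
  }

  if ("stats" %in% stages) {
    results$clusters <- pipeline_cluster_stats(results, config)
    jsonlite::write_json(results$clusters, file.path(out_dir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  files <- list.files(out_dir, pattern = "\\.(csv|json|yaml)$",
                      full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadcoh")),
    seed = config$seed,
    stages = stages,
    n_participants = nrow(participants),
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

# Subject x frequency matrix of channel-averaged coherence for one kind.
subject_freq_matrix <- function(coh, kinds, conditions = NULL) {
  sub <- coh[coh$kind %in% kinds, ]
  if (!is.null(conditions)) sub <- sub[sub$condition %in% conditions, ]
  agg <- dplyr::summarise(
    dplyr::group_by(sub, .data$participant, .data$freq),
    coherence = mean(.data$coherence, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "freq",
                             values_from = "coherence")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$participant
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

pipeline_cluster_stats <- function(results, config) {
  coh <- results$coherence
  real <- subject_freq_matrix(coh, "real", config$conditions)
  surr <- subject_freq_matrix(coh, "surrogate")
  surr <- surr[rownames(real), , drop = FALSE]
  freqs <- as.numeric(colnames(real))

  out <- list()
  cl1 <- cluster_permutation(real, surr, freqs = freqs, type = "paired_t",
                             n_perm = config$n_perm, alpha = config$alpha,
                             seed = derive_seed(config$seed, "stats", 1))
  out$real_vs_surrogate <- c(glance(cl1), list(clusters = tidy(cl1)))

  pw <- results$error_power
  designated <- intersect(config$conditions, c("follower", "leader"))
  if (length(designated) > 0 && "joint" %in% config$conditions) {
    pw_wide <- function(conds) {
      sub <- pw[pw$condition %in% conds, ]
      agg <- dplyr::summarise(
        dplyr::group_by(sub, .data$participant, .data$freq),
        power = mean(.data$power), .groups = "drop")
      w <- tidyr::pivot_wider(agg, names_from = "freq", values_from = "power")
      m <- as.matrix(w[, -1]); rownames(m) <- w$participant
      m[, order(as.numeric(colnames(m))), drop = FALSE]
    }
    a <- pw_wide(designated); b <- pw_wide("joint")[rownames(a), , drop = FALSE]
    cl2 <- cluster_permutation(a, b, freqs = as.numeric(colnames(a)),
                               type = "paired_t", n_perm = config$n_perm,
                               alpha = config$alpha,
                               seed = derive_seed(config$seed, "stats", 2))
    out$power_designated_vs_joint <- c(glance(cl2), list(clusters = tidy(cl2)))
  }

  pow_all <- {
    agg <- dplyr::summarise(
      dplyr::group_by(pw[pw$condition %in% config$conditions, ],
                      .data$participant, .data$freq),
      power = mean(.data$power), .groups = "drop")
    w <- tidyr::pivot_wider(agg, names_from = "freq", values_from = "power")
    m <- as.matrix(w[, -1]); rownames(m) <- w$participant
    m[, order(as.numeric(colnames(m))), drop = FALSE]
  }
  pow_all <- pow_all[rownames(real), , drop = FALSE]
  if (nrow(real) >= 4) {
    cl3 <- cluster_permutation(real, pow_all, freqs = freqs,
                               type = "correlation", n_perm = config$n_perm,
                               alpha = config$alpha,
                               seed = derive_seed(config$seed, "stats", 3))
    out$coherence_vs_error_power <- c(glance(cl3), list(clusters = tidy(cl3)))
  }
  out
}

#' Summarize a completed pipeline run
#'
#' Reads the tables a [run_pipeline()] call wrote and returns one row per
#' condition with the mean band-averaged coherence, coherence/error-power
#' ratio, and per-group peak coherence and peak lag, plus (as attribute
#' `"clusters"`) the cluster report if present.
#'
#' @param out_dir Directory of a completed run.
#' @return A tibble, one row per condition x channel group.
#' @export
summarize_run <- function(out_dir) {
  band_path <- file.path(out_dir, "band_average.csv")
  if (!dir.exists(out_dir) || !file.exists(band_path)) {
    rlang::abort(paste0("no runs found in ", out_dir,
                        " (missing band_average.csv; run the pipeline first)"))
  }
  band <- utils::read.csv(band_path)
  real <- band[band$kind == "real", ]
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(real), .data$condition),
    band_coherence = mean(.data$coherence, na.rm = TRUE), .groups = "drop")
  baseline <- band[band$kind == "surrogate", ]
  if (nrow(baseline) > 0) {
    tab$baseline_coherence <- mean(baseline$coherence, na.rm = TRUE)
  }
  ratio_path <- file.path(out_dir, "coherence_power_ratio.csv")
  if (file.exists(ratio_path)) {
    ratio <- tibble::as_tibble(utils::read.csv(ratio_path))
    rtab <- dplyr::summarise(dplyr::group_by(ratio, .data$condition),
                             coherence_power_ratio = mean(.data$ratio, na.rm = TRUE),
                             .groups = "drop")
    tab <- dplyr::left_join(tab, rtab, by = "condition")
  }
  peaks_path <- file.path(out_dir, "lag_peaks.csv")
  if (file.exists(peaks_path)) {
    pk <- tibble::as_tibble(utils::read.csv(peaks_path))
    ptab <- dplyr::summarise(dplyr::group_by(pk, .data$condition, .data$group),
                             peak_coh = mean(.data$peak_coh, na.rm = TRUE),
                             peak_lag = mean(.data$peak_lag, na.rm = TRUE),
                             .groups = "drop")
    tab <- dplyr::left_join(tab, ptab, by = "condition")
  }
  cl_path <- file.path(out_dir, "clusters.json")
  if (file.exists(cl_path)) {
    attr(tab, "clusters") <- jsonlite::read_json(cl_path, simplifyVector = TRUE)
  }
  tab
}
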