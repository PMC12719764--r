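# Plain-text trial container: one directory per trial with motion and EEG
# as CSV plus a JSON metadata sidecar. Keeps every artifact diffable and
# language-agnostic.

#' Write a dyad trial to a directory container
#'
#' Layout: `motion.csv` (columns `pos_a_x, pos_a_y, pos_b_x, pos_b_y`),
#' `eeg_a.csv` / `eeg_b.csv` (one column per channel), `error.csv`, and
#' `meta.json` holding the condition, sampling rates, and the generating
#' configuration.
#'
#' @param trial A `dyad_trial`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot_msg(inherits(trial, "dyad_trial"), "trial must be a dyad_trial")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  motion <- data.frame(pos_a_x = trial$pos_a[, 1], pos_a_y = trial$pos_a[, 2],
                       pos_b_x = trial$pos_b[, 1], pos_b_y = trial$pos_b[, 2])
  utils::write.csv(motion, file.path(dir, "motion.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(t(trial$eeg_a)), file.path(dir, "eeg_a.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(t(trial$eeg_b)), file.path(dir, "eeg_b.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(error = trial$error$values),
                   file.path(dir, "error.csv"), row.names = FALSE)
  meta <- trial$ground_truth
  class(meta) <- NULL
  jsonlite::write_json(list(condition = trial$condition, config = meta),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a dyad trial from a directory container
#'
#' @param dir Directory written by [write_trial()].
#' @return A `dyad_trial`.
#' @export
read_trial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  # non-finite values (e.g. an Inf tracking band) serialize to null: fall
  # back to the constructor defaults for those fields
  fields <- meta$config[!vapply(meta$config, is.null, logical(1))]
  cfg <- do.call(dyad_config, fields)
  motion <- utils::read.csv(file.path(dir, "motion.csv"))
  eeg_a <- t(as.matrix(utils::read.csv(file.path(dir, "eeg_a.csv"))))
  eeg_b <- t(as.matrix(utils::read.csv(file.path(dir, "eeg_b.csv"))))
  rownames(eeg_a) <- sprintf("ch%02d", seq_len(nrow(eeg_a)))
  rownames(eeg_b) <- sprintf("ch%02d", seq_len(nrow(eeg_b)))
  err <- utils::read.csv(file.path(dir, "error.csv"))$error
  structure(list(
    pos_a = as.matrix(motion[, c("pos_a_x", "pos_a_y")]),
    pos_b = as.matrix(motion[, c("pos_b_x", "pos_b_y")]),
    eeg_a = eeg_a, eeg_b = eeg_b,
    error = structure(list(values = err, fs = cfg$fs_eeg,
                           trial_id = NA_character_,
                           condition = meta$condition),
                      class = "error_series"),
    condition = meta$condition, ground_truth = cfg
  ), class = "dyad_trial")
}

#' Read a dyad configuration from a YAML or JSON file
#'
#' Keys mirror the [dyad_config()] argument names; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `dyad_config`.
#' @export
read_dyad_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(dyad_config))
  unknown <- setdiff(names(vals), known)
  stopifnot_msg(length(unknown) == 0,
                paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  do.call(dyad_config, vals)
}
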