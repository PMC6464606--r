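#' Read and write tidy trial tables
#'
#' Trial tables are stored as tidy CSV, one row per trial, columns exactly
#' as produced by the simulator; timestamps are seconds from session start.
#' The round trip is lossless.
#'
#' @param trials trial table.
#' @param path CSV path.
#' @return `read_trials` returns the trial table as a data.frame.
#' @export
write_trials <- function(trials, path) {
  data.table::fwrite(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- as.data.frame(data.table::fread(path,
                                         na.strings = c("NA", "")))
  for (col in c("site_id", "session_id", "trial_index", "block_id",
                "high_side", "choice", "prev_choice"))
    if (col %in% names(out) && is.logical(out[[col]]))
      out[[col]] <- as.character(out[[col]])
  out
}

#' Write and read a photometry trace as CSV with a JSON sidecar
#'
#' The samples go to `<path>` (columns `sample_index`, `raw_f`); site id,
#' sampling rate and session offsets go to `<path>.json`.
#'
#' @param trace a `photometry_trace`.
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  data.table::fwrite(data.frame(sample_index = seq_along(trace$samples),
                                raw_f = trace$samples), path)
  jsonlite::write_json(list(site_id = trace$site_id,
                            sampling_rate = trace$sampling_rate,
                            session_offsets = trace$session_offsets,
                            session_ids = trace$session_ids),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- data.table::fread(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(site_id = meta$site_id,
                 sampling_rate = meta$sampling_rate,
                 samples = d$raw_f,
                 session_offsets = as.integer(meta$session_offsets),
                 session_ids = meta$session_ids),
            class = "photometry_trace")
}

#' Map lever side to the contra/ipsi frame of a recording hemisphere
#'
#' @param lever_side `"left"` or `"right"` (vectorised).
#' @param hemisphere recording hemisphere, `"left"` or `"right"`.
#' @return `"contra"` or `"ipsi"`.
#' @export
side_to_frame <- function(lever_side, hemisphere) {
  if (!hemisphere %in% c("left", "right"))
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  ifelse(lever_side == hemisphere, "ipsi", "contra")
}

#' Load a task/photometry configuration from YAML
#'
#' Recognised top-level keys: `task`, `photometry`, `fit`; each is passed as
#' arguments to the corresponding constructor, so every field defaults as
#' documented there.
#'
#' @param path YAML file.
#' @return list with `task`, `photometry`, `fit` config objects.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  list(task = do.call(task_config, y$task %||% list()),
       photometry = do.call(photometry_config, y$photometry %||% list()),
       fit = do.call(fit_config, y$fit %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
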