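recording_columns <- function() {
  c("time_s", "current_mA", "map_mmHg", "hr_bpm", "cbf_pu")
}

sidecar_path <- function(path) paste0(path, ".meta")

#' Write a recording to CSV with a metadata sidecar
#'
#' The trace goes to `path` as a CSV with header
#' `time_s,current_mA,map_mmHg,hr_bpm,cbf_pu`; the animal id, group,
#' responder flag, seed and sample rate go to a `key: value` text sidecar at
#' `<path>.meta`.
#'
#' @param rec A `physio_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  meta <- recording_meta(rec)
  readr::write_csv(tibble::as_tibble(rec)[recording_columns()], path)
  writeLines(
    sprintf("%s: %s", names(meta),
            vapply(meta, function(v) format(v, scientific = FALSE), character(1))),
    sidecar_path(path)
  )
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Validates the header, rejects missing values, and enforces a strictly
#' increasing uniform time grid (relative step tolerance 1e-6).
#'
#' @param path CSV path (sidecar expected at `<path>.meta`).
#' @return A `physio_recording`.
#' @export
read_recording <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(recording_columns(), names(dat))
  if (length(missing_cols) > 0) {
    abort(sprintf("Recording %s is missing column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  dat <- dat[recording_columns()]
  for (col in recording_columns()) {
    bad <- which(!is.finite(dat[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Recording %s: non-finite value in column %s, row %d.",
                    path, col, bad[1]))
    }
  }
  tryCatch(check_uniform_grid(dat$time_s),
           error = function(e) {
             abort(sprintf("Recording %s: %s", path, conditionMessage(e)))
           })
  meta <- list(animal_id = NA_character_, group = NA_character_,
               responder = NA, seed = NA_integer_, sample_rate = NA_real_)
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    kv <- readLines(sp)
    kv <- kv[nzchar(trimws(kv))]
    keys <- trimws(sub(":.*$", "", kv))
    vals <- trimws(sub("^[^:]*:", "", kv))
    parsed <- stats::setNames(as.list(vals), keys)
    meta$animal_id <- parsed$animal_id %||% meta$animal_id
    meta$group <- parsed$group %||% meta$group
    if (!is.null(parsed$responder)) meta$responder <- as.logical(parsed$responder)
    if (!is.null(parsed$seed)) meta$seed <- as.integer(parsed$seed)
    if (!is.null(parsed$sample_rate)) meta$sample_rate <- as.numeric(parsed$sample_rate)
  }
  if (is.na(meta$sample_rate)) {
    meta$sample_rate <- 1 / diff(dat$time_s[1:2])
  }
  new_physio_recording(dat, meta = meta)
}

#' Assemble a pipeline run configuration
#'
#' @param stimulus A [stimulus_spec()].
#' @param cohort A [cohort_spec()].
#' @param params Named list of [response_params()] keyed by group label;
#'   groups not listed use [preset_params()].
#' @param detector Named list of detector settings: `k_sd`, `min_duration`,
#'   `smoothing_halfwidth`, `oscillation_threshold`, `decrease_threshold`.
#' @param windows Analysis windows tibble, default [standard_windows()].
#' @param output_dir Directory for the persisted CSV tables, or `NULL` to
#'   keep everything in memory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(stimulus = stimulus_spec(),
                       cohort = cohort_spec(),
                       params = NULL,
                       detector = list(),
                       windows = standard_windows(),
                       output_dir = NULL) {
  det <- modifyList(
    list(k_sd = 3, min_duration = 15, smoothing_halfwidth = 1,
         oscillation_threshold = 20, decrease_threshold = -2),
    detector
  )
  for (nm in c("k_sd", "min_duration", "smoothing_halfwidth",
               "oscillation_threshold")) {
    if (det[[nm]] <= 0) abort(sprintf("Detector setting `%s` must be > 0.", nm))
  }
  if (!is.null(params)) {
    unknown <- setdiff(names(params), recognized_groups())
    if (length(unknown) > 0) {
      abort(sprintf("`params` refers to unrecognized group(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
  }
  structure(list(stimulus = stimulus, cohort = cohort, params = params,
                 detector = det, windows = windows, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the constructor fields: `stimulus`, `cohort`, `params` (one
#' block of [response_params()] overrides per group), `detector`,
#' `output_dir`. Anything omitted falls back to the defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stim <- do.call(stimulus_spec, cfg$stimulus %||% list())
  coh <- do.call(cohort_spec, cfg$cohort %||% list())
  params <- NULL
  if (!is.null(cfg$params)) {
    params <- purrr::imap(cfg$params, function(overrides, g) {
      do.call(response_params,
              modifyList(unclass(preset_params(g)), overrides))
    })
  }
  run_config(stimulus = stim, cohort = coh, params = params,
             detector = cfg$detector %||% list(),
             output_dir = cfg$output_dir)
}
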