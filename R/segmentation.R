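#' Construct an analysis window
#'
#' Windows are half-open intervals `[t_start, t_end)` so adjacent windows
#' never double-count boundary samples.
#'
#' @param name Window label.
#' @param t_start,t_end Window bounds in seconds, `t_end > t_start`.
#' @return A one-row tibble with columns `window`, `t_start`, `t_end`.
#' @export
section_window <- function(name, t_start, t_end) {
  if (t_end <= t_start) abort("`t_end` must be > `t_start`.")
  tibble::tibble(window = as.character(name), t_start = t_start, t_end = t_end)
}

#' The standard analysis windows of a 37-minute session
#'
#' Baseline (minutes 0-4), Stimulation (minutes 4-7), and the Post-Stimulation
#' period subdivided into 0-5, 5-10, 10-20 and 20-30 minutes after
#' stimulation ends. Stimulation is taken to start at minute 4, immediately
#' after the 4-minute baseline.
#'
#' @return A six-row tibble of [section_window()] rows, pairwise disjoint and
#'   ordered in time.
#' @examples
#' standard_windows()
#' @export
standard_windows <- function() {
  dplyr::bind_rows(
    section_window("Baseline", 0, 240),
    section_window("Stimulation", 240, 420),
    section_window("Post0-5", 420, 720),
    section_window("Post5-10", 720, 1020),
    section_window("Post10-20", 1020, 1620),
    section_window("Post20-30", 1620, 2220)
  )
}

window_indices <- function(time, window) {
  which(time >= window$t_start & time < window$t_end)
}

#' Per-window, per-channel mean and SD
#'
#' Averages each physiological channel (MAP, HR, CBF) over the samples falling
#' in the half-open window and computes the sample SD (n-1 denominator). The
#' stimulation-current channel is not summarized.
#'
#' @param rec A `physio_recording` (or any data frame with a `time_s` column
#'   and the physiological channels).
#' @param window A one-row window tibble, e.g. a row of [standard_windows()].
#' @return A tibble with one row per channel: `window`, `channel`, `mean`,
#'   `sd`, `n_samples`.
#' @seealso [summarize_sections()] to cover several windows,
#'   [percent_change()] to reference the summaries to baseline.
#' @export
summarize_section <- function(rec, window) {
  stopifnot(is.data.frame(window), nrow(window) == 1)
  idx <- window_indices(rec$time_s, window)
  if (length(idx) == 0) {
    abort(sprintf("Window \"%s\" [%g, %g) contains no samples of the recording.",
                  window$window, window$t_start, window$t_end))
  }
  if (window$t_end > max(rec$time_s) + diff(rec$time_s[1:2])) {
    abort(sprintf("Window \"%s\" extends past the end of the recording (%g s).",
                  window$window, max(rec$time_s)))
  }
  purrr::map_dfr(physio_channels(), function(ch) {
    x <- rec[[ch]][idx]
    tibble::tibble(window = window$window, channel = ch,
                   mean = mean(x), sd = stats::sd(x),
                   n_samples = length(x))
  })
}

#' Summarize a recording over several windows
#'
#' @param rec A `physio_recording`.
#' @param windows A tibble of windows, default [standard_windows()].
#' @return A tibble stacking [summarize_section()] over all windows, carrying
#'   the recording's animal id and group when available.
#' @export
summarize_sections <- function(rec, windows = standard_windows()) {
  out <- purrr::map_dfr(seq_len(nrow(windows)),
                        function(i) summarize_section(rec, windows[i, ]))
  meta <- attr(rec, "meta")
  if (!is.null(meta)) {
    out <- dplyr::mutate(out, animal = meta$animal_id, group = meta$group,
                         .before = 1)
  }
  out
}

#' Percent change from the baseline window
#'
#' Adds `pct_change = 100 * (mean - baseline mean) / baseline mean` per
#' channel, where the baseline mean is the summary row of the named baseline
#' window. The baseline window's own `pct_change` is exactly 0.
#'
#' @param summaries Output of [summarize_sections()] (may stack several
#'   animals if it has an `animal` column).
#' @param baseline Name of the baseline window, default `"Baseline"`.
#' @return `summaries` with a `pct_change` column (%).
#' @examples
#' rec <- simulate_session(group = "sgvs", seed = 1)
#' summarize_sections(rec) |> percent_change()
#' @export
percent_change <- function(summaries, baseline = "Baseline") {
  if (!baseline %in% summaries$window) {
    abort(sprintf("Baseline window \"%s\" not found in `summaries`.", baseline))
  }
  by <- intersect(c("animal", "channel"), names(summaries))
  base <- summaries |>
    dplyr::filter(.data$window == baseline) |>
    dplyr::select(dplyr::all_of(by), base_mean = "mean")
  if (any(base$base_mean == 0)) {
    abort("Baseline mean is zero for at least one channel; percent change undefined.")
  }
  summaries |>
    dplyr::left_join(base, by = by) |>
    dplyr::mutate(pct_change = 100 * (.data$mean - .data$base_mean) / .data$base_mean) |>
    dplyr::select(-"base_mean")
}
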