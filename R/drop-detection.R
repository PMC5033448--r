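#' Baseline reference statistics for the drop detector
#'
#' Per-channel mean and sample SD over the baseline window; these define the
#' `mean - k*SD` threshold the sustained-drop criterion is referenced to.
#'
#' @param rec A `physio_recording`.
#' @param baseline A one-row window tibble (default the standard Baseline,
#'   minutes 0-4).
#' @return A tibble with columns `channel`, `mean`, `sd` and the source
#'   window as attribute `"window"`.
#' @export
baseline_stats <- function(rec, baseline = standard_windows()[1, ]) {
  s <- summarize_section(rec, baseline)
  if (any(s$sd == 0)) {
    abort(sprintf(
      "Degenerate baseline: channel(s) %s have zero SD; detector thresholds are undefined.",
      paste(s$channel[s$sd == 0], collapse = ", ")))
  }
  out <- dplyr::select(s, "channel", "mean", "sd")
  attr(out, "window") <- baseline
  out
}

# centered moving average with shrinking edge windows (no NA padding)
smooth_ma <- function(x, halfwidth_samples) {
  h <- as.integer(halfwidth_samples)
  if (h <= 0) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Local minima of a (smoothed) signal
#'
#' Finds the times where the smoothed signal is less than or equal to both
#' neighbors. Runs of exactly equal values (plateaus) are resolved to their
#' first sample. The first/last sample counts as a minimum when it does not
#' exceed its single neighbor, so a strictly decreasing signal yields one
#' candidate at its end.
#'
#' @param signal Numeric vector.
#' @param time Numeric time vector of the same length (uniform grid).
#' @param smoothing_halfwidth Half-width of the centered moving average, in
#'   seconds; 0 disables smoothing.
#' @return Tibble with columns `time`, `value` (smoothed value), `index`,
#'   in time order.
#' @export
find_local_minima <- function(signal, time, smoothing_halfwidth = 0) {
  stopifnot(length(signal) == length(time), length(signal) >= 1)
  if (length(signal) == 1) {
    return(tibble::tibble(time = time, value = signal, index = 1L))
  }
  dt <- check_uniform_grid(time)
  s <- smooth_ma(signal, round(smoothing_halfwidth / dt))
  r <- rle(s)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  left <- c(Inf, r$values[-k])    # boundary runs treated as minima-eligible
  right <- c(r$values[-1], Inf)
  is_min <- r$values <= left & r$values <= right
  idx <- starts[is_min]
  tibble::tibble(time = time[idx], value = s[idx], index = idx)
}

#' Detect a sustained drop below baseline
#'
#' Implements the two-criterion excursion test used for the CBF syncope-onset
#' surrogate: among the local minima of the (smoothed) channel inside the
#' stimulation window, the first whose value lies more than `k_sd` baseline
#' SDs below the baseline mean *and* whose surrounding excursion keeps the
#' signal below the sustain level for more than `min_duration` contiguous
#' seconds is returned. The sustain level defaults to the same
#' `mean - k_sd*SD` threshold as the depth criterion (`sustain =
#' "threshold"`); `sustain = "baseline"` uses the laxer below-baseline-mean
#' reading.
#'
#' @param rec A `physio_recording`.
#' @param channel Channel to examine, default `"cbf_pu"`.
#' @param stim_window One-row window tibble; local minima are only sought
#'   here. Defaults to the standard Stimulation window.
#' @param base [baseline_stats()] of the same recording (computed if omitted).
#' @param k_sd Depth criterion in baseline SDs, default 3.
#' @param min_duration Minimum sustained time below the sustain level,
#'   seconds, default 15.
#' @param smoothing_halfwidth Seconds of centered-moving-average smoothing
#'   applied before locating minima (default 1 s; use 0 for noise-free
#'   constructed traces).
#' @param sustain `"threshold"` or `"baseline"` (see Details).
#' @return A one-row tibble (`channel`, `t_min_s`, `delay_s`, `depth_sd`,
#'   `depth_pct`, `sustained_s`) for the first qualifying minimum, or a
#'   zero-row tibble when none qualifies. `delay_s` is measured from the
#'   window start (the stimulation onset).
#' @examples
#' rec <- simulate_session(group = "sgvs", seed = 3, responder = TRUE)
#' detect_sustained_drop(rec)
#' @export
detect_sustained_drop <- function(rec, channel = "cbf_pu",
                                  stim_window = standard_windows()[2, ],
                                  base = baseline_stats(rec),
                                  k_sd = 3, min_duration = 15,
                                  smoothing_halfwidth = 1,
                                  sustain = c("threshold", "baseline")) {
  sustain <- match.arg(sustain)
  if (!channel %in% names(rec)) {
    abort(sprintf("Channel \"%s\" not found in the recording.", channel))
  }
  b <- base[base$channel == channel, ]
  if (nrow(b) != 1) abort(sprintf("No baseline stats for channel \"%s\".", channel))
  dt <- check_uniform_grid(rec$time_s)
  s <- smooth_ma(rec[[channel]], round(smoothing_halfwidth / dt))
  thr <- b$mean - k_sd * b$sd
  level <- if (sustain == "threshold") thr else b$mean

  in_win <- rec$time_s >= stim_window$t_start & rec$time_s < stim_window$t_end
  cand <- find_local_minima(s[in_win], rec$time_s[in_win],
                            smoothing_halfwidth = 0)
  cand <- cand[cand$value < thr, ]
  empty <- tibble::tibble(channel = character(), t_min_s = double(),
                          delay_s = double(), depth_sd = double(),
                          depth_pct = double(), sustained_s = double())
  if (nrow(cand) == 0) return(empty)

  below <- s < level
  run <- rle(below)
  run_id <- rep(seq_along(run$lengths), run$lengths)
  for (i in seq_len(nrow(cand))) {
    gi <- which(rec$time_s == cand$time[i])  # index in the full trace
    if (!below[gi]) next
    dur <- run$lengths[run_id[gi]] * dt
    if (dur > min_duration) {
      return(tibble::tibble(
        channel = channel,
        t_min_s = cand$time[i],
        delay_s = cand$time[i] - stim_window$t_start,
        depth_sd = (b$mean - cand$value[i]) / b$sd,
        depth_pct = 100 * (b$mean - cand$value[i]) / b$mean,
        sustained_s = dur
      ))
    }
  }
  empty
}

#' Delay of a drop event from stimulation onset
#'
#' @param event A one-row drop-event tibble from [detect_sustained_drop()].
#' @param onset Stimulation onset, seconds.
#' @return Delay in seconds (`t_min_s - onset`).
#' @export
drop_delay <- function(event, onset) {
  stopifnot(is.data.frame(event), nrow(event) == 1)
  if (event$t_min_s < onset) {
    abort("Event minimum precedes the stimulation onset.")
  }
  event$t_min_s - onset
}

#' Summarize drop delays across a cohort
#'
#' @param events A tibble of drop events (one row per detected event) with a
#'   `delay_s` column, e.g. stacked outputs of [detect_sustained_drop()].
#' @return A one-row tibble: `n_events`, `mean_delay_s`, `sd_delay_s`.
#' @export
cohort_delay_summary <- function(events) {
  if (!is.data.frame(events) || !"delay_s" %in% names(events)) {
    abort("`events` must be a drop-event tibble with a `delay_s` column.")
  }
  if (nrow(events) < 2) {
    abort("At least 2 drop events are required to summarize delays.")
  }
  tibble::tibble(n_events = nrow(events),
                 mean_delay_s = mean(events$delay_s),
                 sd_delay_s = stats::sd(events$delay_s))
}
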