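fixture_recording <- function(cbf_window, seed, animal_id) {
  fs <- 10
  n <- 120 * fs
  time <- (seq_len(n) - 1) / fs
  noise <- withr::with_seed(seed, {
    list(map = rnorm(n, sd = 1), hr = rnorm(n, sd = 3), cbf = rnorm(n, sd = 20))
  })
  in_base <- time < 30
  cbf <- rep(1780, n)
  cbf[in_base] <- 1780 + noise$cbf[in_base]   # noise-free analysis window
  cbf[!in_base] <- cbf_window(time[!in_base])
  rec <- tibble::tibble(
    time_s = time,
    current_mA = numeric(n),
    map_mmHg = 90 + noise$map,
    hr_bpm = 350 + noise$hr,
    cbf_pu = cbf
  )
  new_physio_recording(rec, meta = list(animal_id = animal_id, group = "sgvs",
                                        responder = TRUE, seed = seed,
                                        sample_rate = fs))
}

#' Miniature constructed test recordings
#'
#' Deterministic 120-second, 10 Hz sessions with a noisy baseline over
#' `[0, 30)` s (so baseline SDs are well defined, CBF SD near 20 PU) and a
#' noise-free constructed CBF trace over the analysis window `[30, 120)`:
#'
#' * `step_5sd_30s` — CBF steps from 1780 to 1680 PU (about 5 baseline SDs)
#'   at t = 90 s for 30 s: the detector fires with delay 60 s from the
#'   window start.
#' * `step_5sd_10s` — same depth but only 10 s long: fails the sustain
#'   criterion.
#' * `step_2sd_60s` — a 40 PU step (about 2 SDs) for 60 s: fails the depth
#'   criterion.
#' * `flat` — constant at baseline: no excursion at all.
#'
#' Use `smoothing_halfwidth = 0` with these: the constructed windows are
#' noise-free, and unsmoothed detection recovers the step onset exactly.
#'
#' @param seed Seed for the baseline noise.
#' @return Named list of `physio_recording`s, plus an attribute `window`
#'   holding the `[30, 120)` analysis window and `baseline` holding the
#'   `[0, 30)` baseline window.
#' @examples
#' fx <- make_fixtures()
#' names(fx)
#' @export
make_fixtures <- function(seed = 20160922) {
  step <- function(at, depth, len) {
    force(at); force(depth); force(len)
    function(t) 1780 - depth * (t >= at & t < at + len)
  }
  fx <- list(
    step_5sd_30s = fixture_recording(step(90, 100, 30), seed, "step_5sd_30s"),
    step_5sd_10s = fixture_recording(step(90, 100, 10), seed + 1, "step_5sd_10s"),
    step_2sd_60s = fixture_recording(step(60, 40, 60), seed + 2, "step_2sd_60s"),
    flat = fixture_recording(function(t) rep(1780, length(t)), seed + 3, "flat")
  )
  attr(fx, "window") <- section_window("Window", 30, 120)
  attr(fx, "baseline") <- section_window("Baseline", 0, 30)
  fx
}
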