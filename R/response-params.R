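#' Generative parameters of one group's vasovagal response
#'
#' Bundles everything the session simulator needs to draw one animal's
#' response: channel baselines, the distributions of the effect sizes and of
#' the cerebral-blood-flow (CBF) drop delay, the probabilities of the early
#' transient heart-rate rise and of a slow pre-drop CBF decline, recovery time
#' constants, anesthesia drift, the stimulus-locked oscillation amplitude, the
#' white-noise level, and the probability that an animal responds at all.
#'
#' Effect sizes (`map_drop_frac`, `hr_drop_frac`, `cbf_drop_frac`) are the
#' *programmed stimulation-window mean fractional reductions* of each channel
#' relative to the baseline window, i.e. the quantity the percent-change
#' summaries of the analysis pipeline estimate. Per animal the simulator draws
#' the effect from a normal distribution with the given mean and SD and then
#' calibrates the underlying plateau depth so that the noise-free
#' stimulation-window mean change equals the draw (see
#' [simulate_session()]).
#'
#' @param baseline_map,baseline_hr,baseline_cbf Channel baselines: mean
#'   arterial pressure (mmHg), heart rate (bpm), CBF (perfusion units). All
#'   must be > 0.
#' @param map_drop_frac,hr_drop_frac,cbf_drop_frac Mean fractional reduction
#'   of the stimulation-window mean, in `[0, 1)`.
#' @param map_drop_sd,hr_drop_sd,cbf_drop_sd Across-animal SD of the effect
#'   draws (same scale), >= 0.
#' @param cbf_delay_mean,cbf_delay_sd Delay from stimulation onset to the
#'   completed rapid CBF drop, seconds (mean and SD of the normal draw).
#' @param phase1_prob Probability of a brief (< 20 s) heart-rate rise at
#'   stimulation onset.
#' @param gradual_decline_prob Probability of a slow CBF decline preceding the
#'   rapid drop.
#' @param gradual_decline_dur_mean,gradual_decline_dur_sd Duration of that
#'   slow decline, seconds.
#' @param map_recovery_tau Post-stimulation MAP relaxation time constant, s.
#' @param hr_recovery_delay Time HR stays depressed after stimulation ends
#'   before relaxing, s.
#' @param cbf_recovery_frac Fraction of the CBF drop recovered after
#'   stimulation, in `[0, 1)` (CBF does not return to baseline).
#' @param drift_map,drift_hr,drift_cbf Linear anesthesia drift per channel,
#'   channel units per minute (typically <= 0).
#' @param osc_amp_frac Stimulus-locked oscillation amplitude on MAP and HR
#'   during stimulation, as a fraction of baseline.
#' @param noise_sd_frac White-noise SD on every physiological channel, as a
#'   fraction of that channel's baseline.
#' @param responder_prob Probability a simulated animal responds to
#'   stimulation at all.
#'
#' @return An object of class `response_params` (named list).
#' @seealso [preset_params()] for the per-group defaults.
#' @export
response_params <- function(baseline_map = 90,
                            baseline_hr = 350,
                            baseline_cbf = 1780,
                            map_drop_frac = 0,
                            map_drop_sd = 0,
                            hr_drop_frac = 0,
                            hr_drop_sd = 0,
                            cbf_drop_frac = 0,
                            cbf_drop_sd = 0,
                            cbf_delay_mean = 51,
                            cbf_delay_sd = 21.7,
                            phase1_prob = 0,
                            gradual_decline_prob = 0,
                            gradual_decline_dur_mean = 21,
                            gradual_decline_dur_sd = 5.6,
                            map_recovery_tau = 60,
                            hr_recovery_delay = 0,
                            cbf_recovery_frac = 0.7,
                            drift_map = 0,
                            drift_hr = 0,
                            drift_cbf = 0,
                            osc_amp_frac = 0,
                            noise_sd_frac = 0.01,
                            responder_prob = 1) {
  p <- as.list(environment())
  fracs <- c("map_drop_frac", "hr_drop_frac", "cbf_drop_frac",
             "cbf_recovery_frac", "osc_amp_frac", "noise_sd_frac")
  probs <- c("phase1_prob", "gradual_decline_prob", "responder_prob")
  for (f in fracs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v >= 1)
      abort(sprintf("`%s` must be a single fraction in [0, 1).", f))
  }
  for (f in probs) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      abort(sprintf("`%s` must be a probability in [0, 1].", f))
  }
  for (b in c("baseline_map", "baseline_hr", "baseline_cbf")) {
    if (p[[b]] <= 0) abort(sprintf("`%s` must be > 0.", b))
  }
  for (s in c("map_drop_sd", "hr_drop_sd", "cbf_drop_sd", "cbf_delay_sd",
              "gradual_decline_dur_sd")) {
    if (p[[s]] < 0) abort(sprintf("`%s` must be >= 0.", s))
  }
  if (p$cbf_delay_mean <= 0) abort("`cbf_delay_mean` must be > 0 (s).")
  if (p$map_recovery_tau <= 0) abort("`map_recovery_tau` must be > 0 (s).")
  if (p$hr_recovery_delay < 0) abort("`hr_recovery_delay` must be >= 0 (s).")
  structure(p, class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat("<response_params>\n")
  cat(sprintf("  baselines: MAP %g mmHg, HR %g bpm, CBF %g PU\n",
              x$baseline_map, x$baseline_hr, x$baseline_cbf))
  cat(sprintf("  effects (window-mean frac): MAP %g±%g, HR %g±%g, CBF %g±%g\n",
              x$map_drop_frac, x$map_drop_sd, x$hr_drop_frac, x$hr_drop_sd,
              x$cbf_drop_frac, x$cbf_drop_sd))
  cat(sprintf("  CBF drop delay: %g ± %g s; responder_prob %g\n",
              x$cbf_delay_mean, x$cbf_delay_sd, x$responder_prob))
  invisible(x)
}

#' Response-parameter presets for the three study groups
#'
#' Returns the documented generative parameters for one of the recognized
#' groups:
#'
#' * `"sham"` — electrodes placed but no current: all effect sizes zero, every
#'   animal a "responder" (there is nothing to fail to respond to), anesthesia
#'   drift on MAP (-0.3%/min) and HR (-0.4%/min) but not CBF.
#' * `"sgvs"` — stimulated: MAP window-mean effect 8%, CBF effect 22% (SD
#'   11.7%), rapid CBF drop completing 51 ± 21.7 s after onset, 7/16 chance of
#'   a brief initial HR rise, 5/16 chance of a slow 21 ± 5.6 s pre-drop CBF
#'   decline, HR depressed for 10 min post-stimulation, 8/10 responder
#'   probability.
#' * `"sgvs_iso_pc"` — stimulated after isoflurane preconditioning: as
#'   `"sgvs"` but with an attenuated CBF effect (12%), a longer drop delay
#'   (72 ± 36.4 s), and HR that recovers as soon as stimulation stops.
#'
#' The HR effect size and the MAP/HR effect SDs are synthetic conventions
#' (no values are reported for them); baseline MAP/HR are physiologically
#' typical anesthetized-rat values, also synthetic conventions.
#'
#' @param group One of `"sham"`, `"sgvs"`, `"sgvs_iso_pc"`.
#' @return A [response_params()] object.
#' @examples
#' preset_params("sgvs")$cbf_delay_mean
#' preset_params("sham")$cbf_drop_frac
#' @export
preset_params <- function(group) {
  if (!is.character(group) || length(group) != 1 ||
      !group %in% recognized_groups()) {
    abort(sprintf("Unknown group %s. Recognized groups: %s.",
                  deparse(substitute(group)),
                  paste0('"', recognized_groups(), '"', collapse = ", ")))
  }
  base <- list(
    baseline_map = 90, baseline_hr = 350, baseline_cbf = 1780,
    drift_map = -0.003 * 90, drift_hr = -0.004 * 350, drift_cbf = 0,
    noise_sd_frac = 0.01
  )
  extra <- switch(group,
    sham = list(responder_prob = 1),
    sgvs = list(
      map_drop_frac = 0.08, map_drop_sd = 0.04,
      hr_drop_frac = 0.10, hr_drop_sd = 0.05,
      cbf_drop_frac = 0.22, cbf_drop_sd = 0.117,
      cbf_delay_mean = 51, cbf_delay_sd = 21.7,
      phase1_prob = 7 / 16,
      gradual_decline_prob = 5 / 16,
      gradual_decline_dur_mean = 21, gradual_decline_dur_sd = 5.6,
      map_recovery_tau = 60, hr_recovery_delay = 600,
      cbf_recovery_frac = 0.7,
      osc_amp_frac = 0.03,
      responder_prob = 8 / 10
    ),
    sgvs_iso_pc = list(
      map_drop_frac = 0.08, map_drop_sd = 0.04,
      hr_drop_frac = 0.10, hr_drop_sd = 0.05,
      cbf_drop_frac = 0.12, cbf_drop_sd = 0.06,
      cbf_delay_mean = 72, cbf_delay_sd = 36.4,
      phase1_prob = 7 / 16,
      gradual_decline_prob = 5 / 16,
      gradual_decline_dur_mean = 21, gradual_decline_dur_sd = 5.6,
      map_recovery_tau = 60, hr_recovery_delay = 0,
      cbf_recovery_frac = 0.7,
      osc_amp_frac = 0.03,
      drift_hr = 0,
      responder_prob = 7 / 10
    )
  )
  do.call(response_params, modifyList(base, extra))
}
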