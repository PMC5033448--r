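# periodogram power of x at frequency f (arbitrary, not only Fourier bins),
# after removing a linear trend: |sum(w (x - trend) e^{-2*pi*i*f*t})|^2 /
# sum(w^2). Normalized so white noise of variance s^2 has expectation ~s^2 at
# any f under either taper, which makes powers from windows of different
# lengths directly comparable. The Hann taper suppresses spectral leakage
# from off-frequency components (the stimulus frequency sits 4.5 bins from
# DC at the default parameters, so a rectangular window would leak harmonics
# and transients into it).
periodogram_power <- function(x, time, f, taper = c("rect", "hann")) {
  taper <- match.arg(taper)
  n <- length(x)
  fit <- stats::lm.fit(cbind(1, time), x)
  r <- fit$residuals
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
       else rep(1, n)
  z <- sum(w * r * exp(-2i * pi * f * time))
  Mod(z)^2 / sum(w^2)
}

#' Stimulus-locked oscillation score
#'
#' Ratio of the periodogram power at the stimulus frequency during the
#' stimulation window to the noise power at that frequency during the
#' baseline window. The baseline (denominator) power is averaged over a
#' narrow band of `2*band_halfwidth + 1` frequencies spaced at the baseline
#' window's resolution and centered on the stimulus frequency, which
#' stabilizes the null distribution of the score (approximately
#' F(2, 2*(2*band_halfwidth+1)) for white noise) without losing frequency
#' selectivity: the first harmonic lies outside the default band. Scores near
#' 1 mean no stimulus-locked oscillation; large scores mean the channel
#' oscillates at the stimulus frequency.
#'
#' @param rec A `physio_recording`.
#' @param channel Channel to score, e.g. `"map_mmHg"`.
#' @param stim A [stimulus_spec()]; its frequency is the probe frequency and
#'   its `[onset, onset+duration)` window is the stimulation window.
#' @param baseline Baseline window tibble (default standard Baseline).
#' @param band_halfwidth Number of baseline-resolution frequency bins on each
#'   side of the stimulus frequency averaged into the denominator (default 3).
#' @return A single dimensionless power ratio.
#' @examples
#' rec <- simulate_session(group = "sgvs", seed = 2, responder = TRUE)
#' oscillation_score(rec, "map_mmHg", stimulus_spec())
#' @export
oscillation_score <- function(rec, channel, stim = stimulus_spec(),
                              baseline = standard_windows()[1, ],
                              band_halfwidth = 3) {
  if (!channel %in% names(rec)) {
    abort(sprintf("Channel \"%s\" not found in the recording.", channel))
  }
  if (stim$duration < 2 / stim$frequency) {
    abort(sprintf(
      "Stimulation window (%g s) is shorter than 2 stimulus periods (%g s); the stimulus frequency cannot be resolved.",
      stim$duration, 2 / stim$frequency))
  }
  t <- rec$time_s
  in_s <- t >= stim$onset & t < stim$onset + stim$duration
  in_b <- t >= baseline$t_start & t < baseline$t_end
  if (!any(in_b)) abort("Baseline window contains no samples.")
  num <- periodogram_power(rec[[channel]][in_s], t[in_s], stim$frequency,
                           taper = "hann")
  t_base_span <- baseline$t_end - baseline$t_start
  offs <- (-band_halfwidth:band_halfwidth) / t_base_span
  freqs <- stim$frequency + offs
  freqs <- freqs[freqs > 0]
  den <- mean(vapply(freqs, function(f) {
    periodogram_power(rec[[channel]][in_b], t[in_b], f)
  }, numeric(1)))
  num / den
}
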