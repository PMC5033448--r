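#' Describe a sinusoidal galvanic vestibular stimulus
#'
#' A stimulus specification holds the amplitude and frequency of the sinusoidal
#' current applied binaurally over the mastoids, plus when it starts and how
#' long it lasts. The default is the 4 mA, 0.025 Hz, 3-minute stimulus applied
#' after a 4-minute baseline, the parameter set that most reliably provokes a
#' vasovagal-like response in anesthetized rats.
#'
#' @param amplitude Peak current, mA (>= 0; 0 encodes "no stimulation").
#' @param frequency Stimulation frequency, Hz (> 0).
#' @param onset Stimulation start, seconds from recording start (>= 0).
#' @param duration Stimulation length, seconds (> 0).
#'
#' @return An object of class `stimulus_spec`: a named list with the four
#'   fields above.
#' @examples
#' stimulus_spec()
#' stimulus_spec(amplitude = 2, frequency = 0.05)
#' @export
stimulus_spec <- function(amplitude = 4, frequency = 0.025, onset = 240,
                          duration = 180) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1,
            is.numeric(frequency), length(frequency) == 1,
            is.numeric(onset), length(onset) == 1,
            is.numeric(duration), length(duration) == 1)
  if (amplitude < 0) abort("`amplitude` must be >= 0 (mA).")
  if (frequency <= 0) abort("`frequency` must be > 0 (Hz).")
  if (onset < 0) abort("`onset` must be >= 0 (s).")
  if (duration <= 0) abort("`duration` must be > 0 (s).")
  structure(
    list(amplitude = amplitude, frequency = frequency,
         onset = onset, duration = duration),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %.3g mA at %.3g Hz, t = [%g, %g) s\n",
              x$amplitude, x$frequency, x$onset, x$onset + x$duration))
  invisible(x)
}

check_uniform_grid <- function(time, tol = 1e-6) {
  if (length(time) < 2) abort("Time grid must have at least 2 samples.")
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > tol * dt[1]) {
    abort("Time grid must be strictly increasing and uniform.")
  }
  dt[1]
}

#' Evaluate a stimulus waveform on a time grid
#'
#' Returns the instantaneous stimulation current
#' \eqn{A \sin(2\pi f (t - t_0))} inside the stimulation window
#' \eqn{[t_0, t_0 + d)} and exactly 0 outside it.
#'
#' @param time Numeric vector, a strictly increasing uniform time grid (s).
#' @param spec A [stimulus_spec()].
#'
#' @return Numeric vector of currents (mA), same length as `time`.
#' @examples
#' t <- seq(0, 600, by = 0.1)
#' i <- make_stimulus_waveform(t, stimulus_spec())
#' max(abs(i))
#' @export
make_stimulus_waveform <- function(time, spec = stimulus_spec()) {
  stopifnot(inherits(spec, "stimulus_spec"))
  check_uniform_grid(time)
  tau <- time - spec$onset
  on <- tau >= 0 & tau < spec$duration
  out <- numeric(length(time))
  out[on] <- spec$amplitude * sin(2 * pi * spec$frequency * tau[on])
  out
}
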