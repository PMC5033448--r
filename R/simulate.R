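# cubic smoothstep on [0, 1]: zero slope at both ends, so a transition that
# "completes at" its right edge really is flat there.
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# winsorize a single normal draw into [lo, hi]
draw_frac <- function(mean, sd, lo = 0.01, hi = 0.95) {
  min(max(rnorm(1, mean, sd), lo), hi)
}

# MAP/HR decline: rises over the first `rise` s of stimulation, holds at 1,
# then relaxes post-stimulation. `hold` is how long the plateau persists
# after stimulation ends before the exponential relaxation starts.
pressor_shape <- function(tau, duration, rise, tau_rec, hold = 0) {
  u <- numeric(length(tau))
  during <- tau >= 0 & tau < duration
  u[during] <- smoothstep(tau[during] / rise)
  post <- tau >= duration
  tp <- tau[post] - duration
  u[post] <- ifelse(tp < hold, 1, exp(-(tp - hold) / tau_rec))
  u
}

# CBF response shape: optional slow pre-drop decline to `gradual_level`,
# rapid smoothstep drop completing exactly at `delay`, plateau at 1 until
# stimulation ends, then partial recovery to (1 - recovery_frac).
cbf_shape <- function(tau, duration, delay, rise, gradual_dur, gradual_level,
                      recovery_frac, tau_rec) {
  u <- numeric(length(tau))
  t_rapid0 <- delay - rise            # rapid drop start
  if (gradual_dur > 0) {
    g0 <- max(0, t_rapid0 - gradual_dur)
    in_g <- tau >= g0 & tau < t_rapid0
    u[in_g] <- gradual_level * (tau[in_g] - g0) / (t_rapid0 - g0)
  }
  in_r <- tau >= t_rapid0 & tau < delay
  u[in_r] <- gradual_level +
    (1 - gradual_level) * smoothstep((tau[in_r] - t_rapid0) / rise)
  u[tau >= delay & tau < duration] <- 1
  post <- tau >= duration
  u[post] <- 1 - recovery_frac * (1 - exp(-(tau[post] - duration) / tau_rec))
  u
}

#' Simulate one physiological recording
#'
#' Generates a complete multichannel session (time, stimulation current, MAP,
#' HR, CBF) on a uniform grid covering the baseline period, the stimulation
#' window, and 30 minutes post-stimulation. Responder sessions superpose, on
#' each channel baseline: linear anesthesia drift; a smooth decline of MAP and
#' HR during stimulation (HR optionally preceded by a brief rise); a delayed
#' rapid CBF drop (optionally preceded by a slow shallow decline) sustained
#' through the window; post-stimulation recovery (MAP relaxes fully, HR stays
#' depressed for a while, CBF recovers only partially); a stimulus-locked
#' sinusoidal oscillation on MAP and HR during stimulation; and white noise on
#' every physiological channel. Non-responders and sham animals get only
#' baseline + drift + noise (sham additionally carries zero current).
#'
#' Effect calibration: the per-animal drawn effect size is imposed as the
#' *noise-free stimulation-window mean percent change from the baseline
#' window*, so the drop plateau is deeper than the drawn effect whenever the
#' CBF drop is delayed (the plateau depth is solved analytically from the
#' drawn delay, the drift, and the oscillation term). This makes the drawn
#' effect exactly the quantity the percent-change pipeline estimates.
#'
#' Identical arguments (including `seed`) give bitwise-identical recordings.
#'
#' @param spec A [stimulus_spec()].
#' @param params A [response_params()]; defaults to `preset_params(group)`.
#' @param group Group label: `"sham"`, `"sgvs"` or `"sgvs_iso_pc"`.
#' @param seed Integer seed for this animal's draws.
#' @param sample_rate Sampling rate, Hz.
#' @param animal_id Optional id string stored in the metadata.
#' @param responder Optional logical overriding the responder draw (used by
#'   [simulate_cohort()], which draws flags at the cohort level).
#'
#' @return A tibble of class `physio_recording` with columns `time_s`,
#'   `current_mA`, `map_mmHg`, `hr_bpm`, `cbf_pu` and a `meta` attribute
#'   (see [recording_meta()]).
#' @examples
#' rec <- simulate_session(group = "sgvs", seed = 1)
#' recording_meta(rec)
#' @export
simulate_session <- function(spec = stimulus_spec(),
                             params = preset_params(group),
                             group = "sgvs",
                             seed = 1L,
                             sample_rate = 10,
                             animal_id = NULL,
                             responder = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"), inherits(params, "response_params"))
  if (!group %in% recognized_groups()) {
    abort(sprintf("Unknown group \"%s\". Recognized groups: %s.", group,
                  paste0('"', recognized_groups(), '"', collapse = ", ")))
  }
  if (sample_rate <= 0) abort("`sample_rate` must be > 0 (Hz).")
  rise_cbf <- 5     # rapid-drop rise time, s
  rise_map <- 15    # MAP/HR decline rise time, s
  hr_tau_rec <- 60  # HR post-depression relaxation constant, s
  total <- spec$onset + spec$duration + 1800
  n <- round(total * sample_rate)
  time <- (seq_len(n) - 1) / sample_rate
  tau <- time - spec$onset
  stimulated <- group != "sham"

  draws <- withr::with_seed(seed, {
    d <- list()
    d$responder <- if (is.null(responder)) runif(1) < params$responder_prob
                   else isTRUE(responder)
    d$f_map <- draw_frac(params$map_drop_frac, params$map_drop_sd)
    d$f_hr <- draw_frac(params$hr_drop_frac, params$hr_drop_sd)
    # responders are, by definition, animals whose CBF drop was observable
    # (the > 3 SD criterion, ~3% of baseline at default noise), so the CBF
    # effect draw is floored above that observability scale
    d$f_cbf <- draw_frac(params$cbf_drop_frac, params$cbf_drop_sd, lo = 0.05)
    # delay must leave room for the rapid drop and end inside the window
    d$delay <- NA_real_
    for (i in seq_len(20)) {
      cand <- rnorm(1, params$cbf_delay_mean, params$cbf_delay_sd)
      if (cand >= rise_cbf && cand <= spec$duration - 1) {
        d$delay <- cand
        break
      }
    }
    if (is.na(d$delay) && d$responder && stimulated) {
      inform(sprintf(
        "seed %d: CBF drop delay could not be drawn inside the stimulation window after 20 attempts; marking session non-responder.",
        seed))
      d$responder <- FALSE
    }
    d$phase1 <- runif(1) < params$phase1_prob
    d$gradual <- runif(1) < params$gradual_decline_prob
    d$gradual_dur <- min(max(rnorm(1, params$gradual_decline_dur_mean,
                                   params$gradual_decline_dur_sd), 5), 120)
    d$noise <- list(map = rnorm(n), hr = rnorm(n), cbf = rnorm(n))
    d
  })

  current <- if (stimulated) make_stimulus_waveform(time, spec)
             else numeric(n)

  # deterministic base: baseline + drift (+ oscillation and HR bump for
  # responders); effect depths are calibrated against window means of this.
  base <- list(
    map_mmHg = params$baseline_map + params$drift_map * time / 60,
    hr_bpm = params$baseline_hr + params$drift_hr * time / 60,
    cbf_pu = params$baseline_cbf + params$drift_cbf * time / 60
  )
  baselines <- c(map_mmHg = params$baseline_map, hr_bpm = params$baseline_hr,
                 cbf_pu = params$baseline_cbf)

  respond <- stimulated && draws$responder
  if (respond) {
    during <- tau >= 0 & tau < spec$duration
    osc <- numeric(n)
    osc[during] <- params$osc_amp_frac *
      sin(2 * pi * spec$frequency * tau[during])
    base$map_mmHg <- base$map_mmHg + params$baseline_map * osc
    base$hr_bpm <- base$hr_bpm + params$baseline_hr * osc
    if (draws$phase1) {
      in_b <- tau >= 0 & tau < 10
      base$hr_bpm[in_b] <- base$hr_bpm[in_b] +
        0.05 * params$baseline_hr * sin(pi * tau[in_b] / 10)
    }
    gdur <- if (draws$gradual) min(draws$gradual_dur, draws$delay - rise_cbf)
            else 0
    shapes <- list(
      map_mmHg = pressor_shape(tau, spec$duration, rise_map,
                               params$map_recovery_tau),
      hr_bpm = pressor_shape(tau, spec$duration, rise_map, hr_tau_rec,
                             hold = params$hr_recovery_delay),
      cbf_pu = cbf_shape(tau, spec$duration, draws$delay, rise_cbf,
                         gradual_dur = gdur, gradual_level = 0.1,
                         recovery_frac = params$cbf_recovery_frac,
                         tau_rec = 60)
    )
    fr <- c(map_mmHg = draws$f_map, hr_bpm = draws$f_hr, cbf_pu = draws$f_cbf)
    idx_b <- time >= 0 & time < spec$onset
    idx_s <- tau >= 0 & tau < spec$duration
    for (ch in physio_channels()) {
      m_b <- mean(base[[ch]][idx_b])
      m_s <- mean(base[[ch]][idx_s])
      u_s <- mean(shapes[[ch]][idx_s])
      # solve (m_s - depth*B*u_s - m_b)/m_b = -f  for the plateau depth
      depth <- (m_s - (1 - fr[[ch]]) * m_b) / (baselines[[ch]] * u_s)
      depth <- min(max(depth, 0), 0.9)
      base[[ch]] <- base[[ch]] - depth * baselines[[ch]] * shapes[[ch]]
    }
  }

  noise_sd <- params$noise_sd_frac * baselines
  rec <- tibble::tibble(
    time_s = time,
    current_mA = current,
    map_mmHg = base$map_mmHg + noise_sd[["map_mmHg"]] * draws$noise$map,
    hr_bpm = base$hr_bpm + noise_sd[["hr_bpm"]] * draws$noise$hr,
    cbf_pu = base$cbf_pu + noise_sd[["cbf_pu"]] * draws$noise$cbf
  )
  new_physio_recording(rec, meta = list(
    animal_id = animal_id %||% sprintf("%s_seed%d", group, seed),
    group = group,
    responder = draws$responder,
    seed = seed,
    sample_rate = sample_rate
  ))
}

new_physio_recording <- function(data, meta) {
  structure(data,
            meta = meta,
            class = c("physio_recording", class(tibble::tibble())))
}

#' Metadata of a recording
#'
#' @param rec A `physio_recording`.
#' @return Named list with `animal_id`, `group`, `responder`, `seed`,
#'   `sample_rate`.
#' @export
recording_meta <- function(rec) {
  m <- attr(rec, "meta")
  if (is.null(m)) abort("`rec` has no recording metadata; is it a physio_recording?")
  m
}

#' Describe a simulated cohort
#'
#' @param n_per_group Animals per group (>= 1).
#' @param groups Character vector of group labels (subset of the recognized
#'   labels; duplicates not allowed).
#' @param sample_rate Sampling rate, Hz.
#' @param master_seed Integer seed from which per-animal seeds are derived.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        groups = c("sham", "sgvs"),
                        sample_rate = 10,
                        master_seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 1)
    abort("`n_per_group` must be >= 1.")
  if (length(groups) == 0 || !all(groups %in% recognized_groups()) ||
      anyDuplicated(groups))
    abort(sprintf("`groups` must be distinct labels among: %s.",
                  paste0('"', recognized_groups(), '"', collapse = ", ")))
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 sample_rate = sample_rate,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of recordings
#'
#' Draws per-animal seeds and responder flags reproducibly from the master
#' seed, then simulates each animal with [simulate_session()].
#'
#' @param cohort A [cohort_spec()].
#' @param spec A [stimulus_spec()] shared by all animals.
#' @param params Optional named list of [response_params()] keyed by group;
#'   groups not listed use [preset_params()].
#' @return A list of `physio_recording` objects, one per animal, with ids of
#'   the form `"<group>_01"`.
#' @examples
#' recs <- simulate_cohort(cohort_spec(n_per_group = 2, master_seed = 7))
#' vapply(recs, function(r) recording_meta(r)$animal_id, character(1))
#' @export
simulate_cohort <- function(cohort = cohort_spec(),
                            spec = stimulus_spec(),
                            params = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n_total <- cohort$n_per_group * length(cohort$groups)
  draws <- withr::with_seed(cohort$master_seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n_total),
         u = runif(n_total))
  })
  i <- 0L
  out <- list()
  for (g in cohort$groups) {
    p <- params[[g]] %||% preset_params(g)
    for (k in seq_len(cohort$n_per_group)) {
      i <- i + 1L
      out[[i]] <- simulate_session(
        spec = spec, params = p, group = g, seed = draws$seeds[i],
        sample_rate = cohort$sample_rate,
        animal_id = sprintf("%s_%02d", g, k),
        responder = draws$u[i] < p$responder_prob
      )
    }
  }
  out
}
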