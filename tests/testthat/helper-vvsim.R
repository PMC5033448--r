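# build a minimal recording with arbitrary channel values on a uniform grid
make_rec <- function(time, map = 90, hr = 350, cbf = 1780, current = 0,
                     group = "sgvs", animal_id = "test", responder = TRUE) {
  n <- length(time)
  rec <- tibble::tibble(
    time_s = time,
    current_mA = rep_len(current, n),
    map_mmHg = rep_len(map, n),
    hr_bpm = rep_len(hr, n),
    cbf_pu = rep_len(cbf, n)
  )
  vvsim:::new_physio_recording(rec, meta = list(
    animal_id = animal_id, group = group, responder = responder,
    seed = 0L, sample_rate = 1 / diff(time[1:2])
  ))
}

# simulate n forced-responder sessions of one group and collect the
# stimulation-window percent changes and detected CBF drop delays
collect_responder_stats <- function(group, n, seed0, sample_rate = 10) {
  params <- preset_params(group)
  purrr::map_dfr(seq_len(n), function(i) {
    rec <- simulate_session(group = group, params = params,
                            seed = seed0 + i, sample_rate = sample_rate,
                            responder = TRUE)
    s <- percent_change(summarize_sections(rec))
    s <- s[s$window == "Stimulation", ]
    ev <- detect_sustained_drop(rec)
    tibble::tibble(
      cbf_pct = s$pct_change[s$channel == "cbf_pu"],
      map_pct = s$pct_change[s$channel == "map_mmHg"],
      detected = nrow(ev) > 0,
      delay_s = if (nrow(ev) > 0) ev$delay_s else NA_real_
    )
  })
}

# brute-force nested least-squares oracle for the balanced two-way ANOVA:
# sums of squares as RSS differences between nested lm fits, F and p from
# the standard ratios. Independent of the cell-means arithmetic under test.
anova_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  rss <- function(form) sum(stats::lm(form)$residuals^2)
  r0 <- rss(y ~ 1)
  rA <- rss(y ~ A)
  rAB <- rss(y ~ A + B)
  rfull <- rss(y ~ A * B)
  ss <- c(r0 - rA, rA - rAB, rAB - rfull, rfull)
  df <- c(nlevels(A) - 1, nlevels(B) - 1,
          (nlevels(A) - 1) * (nlevels(B) - 1),
          length(y) - nlevels(A) * nlevels(B))
  ms <- ss / df
  f <- ms[1:3] / ms[4]
  list(ss = ss, df = df, f = f,
       p = stats::pf(f, df[1:3], df[4], lower.tail = FALSE))
}
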