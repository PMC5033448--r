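test_that("baseline stats are estimated from the baseline window only", {
  set.seed(2)
  time <- seq(0, 599.9, by = 0.1)
  cbf <- c(rnorm(2400, 1780, 20), rep(500, length(time) - 2400))
  rec <- make_rec(time, map = rnorm(length(time), 90, 1),
                  hr = rnorm(length(time), 350, 3), cbf = cbf)
  b <- baseline_stats(rec, section_window("Baseline", 0, 240))
  cb <- b[b$channel == "cbf_pu", ]
  expect_equal(cb$mean, 1780, tolerance = 0.01)  # relative
  expect_equal(cb$sd, 20, tolerance = 0.05)      # consistency of sample SD
  expect_lt(cb$mean, 1790)                       # the 500-PU tail is ignored

  flat <- make_rec(time = 0:299)
  expect_error(baseline_stats(flat, section_window("Baseline", 0, 240)),
               "Degenerate baseline")
})

test_that("local minima follow the plateau and boundary conventions", {
  t <- seq(0, 19.9, by = 0.1)
  # strictly decreasing: single candidate at the window end
  dec <- find_local_minima(seq(100, 1, length.out = length(t)), t)
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$time, t[length(t)])
  # one full cosine cycle: exactly one interior candidate, at the trough
  cosine <- find_local_minima(cos(2 * pi * 0.05 * t), t)
  expect_equal(nrow(cosine), 1L)
  expect_equal(cosine$time, 10)
  # constant signal: one candidate at the window start (plateau rule)
  const <- find_local_minima(rep(5, length(t)), t)
  expect_equal(nrow(const), 1L)
  expect_equal(const$time, 0)
})

test_that("constructed step drops fire exactly per the depth and sustain criteria", {
  fx <- make_fixtures()
  win <- attr(fx, "window")
  base_win <- attr(fx, "baseline")
  detect <- function(rec) {
    detect_sustained_drop(rec, stim_window = win,
                          base = baseline_stats(rec, base_win),
                          smoothing_halfwidth = 0)
  }
  ev <- detect(fx$step_5sd_30s)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$delay_s, 60)            # exact: minimum at t = 90, onset 30
  expect_equal(ev$depth_sd, 5, tolerance = 0.15)
  expect_equal(ev$depth_pct, 100 * 100 / 1780, tolerance = 0.02)
  expect_equal(ev$sustained_s, 30, tolerance = 0.01)

  expect_equal(nrow(detect(fx$step_5sd_10s)), 0L)  # deep but not sustained
  expect_equal(nrow(detect(fx$step_2sd_60s)), 0L)  # sustained but shallow
  expect_equal(nrow(detect(fx$flat)), 0L)          # no excursion at all
})

test_that("raising the depth or duration criterion never adds events", {
  fx <- make_fixtures()
  win <- attr(fx, "window")
  base_win <- attr(fx, "baseline")
  for (rec in fx) {
    base <- baseline_stats(rec, base_win)
    prev <- Inf
    for (k in c(2, 3, 4, 5, 6)) {
      n <- nrow(detect_sustained_drop(rec, stim_window = win, base = base,
                                      k_sd = k, smoothing_halfwidth = 0))
      expect_lte(n, prev)
      prev <- n
    }
    prev <- Inf
    for (d in c(5, 15, 29, 40)) {
      n <- nrow(detect_sustained_drop(rec, stim_window = win, base = base,
                                      min_duration = d,
                                      smoothing_halfwidth = 0))
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("drop delay is the minimum time after onset and shift-invariant", {
  ev <- tibble::tibble(channel = "cbf_pu", t_min_s = 291, delay_s = 51,
                       depth_sd = 5, depth_pct = 10, sustained_s = 30)
  expect_equal(drop_delay(ev, 240), 51)
  expect_equal(drop_delay(dplyr::mutate(ev, t_min_s = 240), 240), 0)
  expect_error(drop_delay(dplyr::mutate(ev, t_min_s = 100), 240), "precedes")

  fx <- make_fixtures()
  rec <- fx$step_5sd_30s
  shifted <- rec
  shifted$time_s <- shifted$time_s + 1000
  win <- attr(fx, "window")
  win_s <- section_window("Window", win$t_start + 1000, win$t_end + 1000)
  base_s <- baseline_stats(shifted, section_window("Baseline", 1000, 1030))
  ev2 <- detect_sustained_drop(shifted, stim_window = win_s, base = base_s,
                               smoothing_halfwidth = 0)
  expect_equal(ev2$delay_s, 60)
})

test_that("missing channels and channels at baseline are handled", {
  fx <- make_fixtures()
  rec <- fx$flat
  expect_error(
    detect_sustained_drop(rec, channel = "icp_mmHg",
                          stim_window = attr(fx, "window")),
    "icp_mmHg")
  # constant-at-baseline channel never fires whatever the smoothing
  ev <- detect_sustained_drop(rec, stim_window = attr(fx, "window"),
                              base = baseline_stats(rec, attr(fx, "baseline")),
                              smoothing_halfwidth = 1)
  expect_equal(nrow(ev), 0L)
})

test_that("cohort delay summaries need two events and compute mean/SD", {
  ev <- tibble::tibble(delay_s = c(50, 52))
  s <- cohort_delay_summary(ev)
  expect_equal(s$mean_delay_s, 51)
  expect_equal(s$sd_delay_s, sqrt(2))
  expect_equal(cohort_delay_summary(tibble::tibble(delay_s = c(40, 40, 40)))$sd_delay_s, 0)
  expect_error(cohort_delay_summary(tibble::tibble(delay_s = 51)), "2")
})
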