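test_that("the standard windows match the session layout and are disjoint", {
  w <- standard_windows()
  expect_equal(w$window[1:2], c("Baseline", "Stimulation"))
  expect_equal(w$t_start[w$window == "Baseline"], 0)
  expect_equal(w$t_end[w$window == "Baseline"], 240)
  expect_equal(c(w$t_start[2], w$t_end[2]), c(240, 420))
  # post subwindows at 0-5 / 5-10 / 10-20 / 20-30 min after stimulation ends
  post <- w[-(1:2), ]
  expect_equal(post$t_start, 420 + c(0, 5, 10, 20) * 60)
  expect_equal(post$t_end, 420 + c(5, 10, 20, 30) * 60)
  # pairwise disjoint and ordered
  expect_true(all(diff(w$t_start) > 0))
  expect_true(all(w$t_end[-nrow(w)] <= w$t_start[-1]))
})

test_that("window summaries are exact on constructed samples", {
  rec <- make_rec(time = 0:9, cbf = c(10, 20, 30, rep(5, 7)))
  s <- summarize_section(rec, section_window("w", 0, 3))
  cbf <- s[s$channel == "cbf_pu", ]
  expect_equal(cbf$mean, 20)
  expect_equal(cbf$sd, 10)   # n-1 denominator
  expect_equal(cbf$n_samples, 3L)

  const <- summarize_section(make_rec(time = 0:9, cbf = 7), section_window("w", 0, 10))
  expect_equal(const$mean[const$channel == "cbf_pu"], 7)
  expect_equal(const$sd[const$channel == "cbf_pu"], 0)
})

test_that("summaries equal a brute-force two-pass computation", {
  set.seed(1)
  x <- rnorm(100, 1780, 25)
  rec <- make_rec(time = seq(0, 9.9, by = 0.1), cbf = x)
  s <- summarize_section(rec, section_window("w", 0, 10))
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  got <- s[s$channel == "cbf_pu", ]
  expect_equal(got$mean, m, tolerance = 1e-9)
  expect_equal(got$sd, sqrt(v), tolerance = 1e-9)
})

test_that("summarizing is idempotent and linear in channel scale", {
  rec <- simulate_session(group = "sgvs", seed = 8, sample_rate = 2)
  w <- standard_windows()
  expect_identical(summarize_sections(rec, w), summarize_sections(rec, w))

  k <- 3.7
  rec_k <- rec
  rec_k$cbf_pu <- k * rec_k$cbf_pu
  s <- percent_change(summarize_sections(rec, w))
  s_k <- percent_change(summarize_sections(rec_k, w))
  cbf <- s$channel == "cbf_pu"
  expect_equal(s_k$mean[cbf], k * s$mean[cbf])
  expect_equal(s_k$sd[cbf], k * s$sd[cbf])
  expect_equal(s_k$pct_change[cbf], s$pct_change[cbf])
})

test_that("degenerate windows are rejected by name", {
  rec <- make_rec(time = 0:9)
  expect_error(summarize_section(rec, section_window("late", 50, 60)), "late")
  expect_error(summarize_section(rec, section_window("over", 5, 100)),
               "past the end")
  expect_error(section_window("bad", 10, 10), "t_end")
})

test_that("percent change is referenced to the baseline window", {
  rec <- make_rec(time = 0:19, cbf = c(rep(1780, 10), rep(1388.4, 10)),
                  map = c(rep(100, 10), rep(92, 10)))
  w <- dplyr::bind_rows(section_window("Baseline", 0, 10),
                        section_window("Stimulation", 10, 20))
  s <- percent_change(summarize_sections(rec, w))
  expect_equal(s$pct_change[s$window == "Baseline"], rep(0, 3))
  stim <- s[s$window == "Stimulation", ]
  expect_equal(stim$pct_change[stim$channel == "map_mmHg"], -8)
  expect_equal(stim$pct_change[stim$channel == "cbf_pu"], -22)

  rec0 <- make_rec(time = 0:19, cbf = c(rep(0, 10), rep(1, 10)))
  expect_error(percent_change(summarize_sections(rec0, w)), "zero")
})
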