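test_that("identical seeds give bitwise-identical recordings", {
  a <- simulate_session(group = "sgvs", seed = 42L)
  b <- simulate_session(group = "sgvs", seed = 42L)
  expect_identical(a, b)
  c <- simulate_session(group = "sgvs", seed = 43L)
  expect_false(identical(a$cbf_pu, c$cbf_pu))
})

test_that("a noise- and drift-free non-responder is constant at baseline", {
  p <- response_params(noise_sd_frac = 0)
  rec <- simulate_session(group = "sgvs", params = p, seed = 1,
                          responder = FALSE)
  expect_true(all(rec$map_mmHg == p$baseline_map))
  expect_true(all(rec$hr_bpm == p$baseline_hr))
  expect_true(all(rec$cbf_pu == p$baseline_cbf))
  # current is still applied: non-responders were stimulated
  expect_gt(max(abs(rec$current_mA)), 0)
})

test_that("current vanishes outside the stimulation window and sham carries none", {
  rec <- simulate_session(group = "sgvs", seed = 5)
  outside <- rec$time_s < 240 | rec$time_s >= 420
  expect_true(all(rec$current_mA[outside] == 0))
  expect_equal(max(abs(rec$current_mA)), 4, tolerance = 1e-3)
  sham <- simulate_session(group = "sham", params = preset_params("sham"),
                           seed = 5)
  expect_true(all(sham$current_mA == 0))
})

test_that("the CBF minimum reaches at least the programmed depth", {
  p <- do.call(response_params, utils::modifyList(
    unclass(preset_params("sgvs")), list(cbf_drop_sd = 0)))
  for (seed in c(2, 9, 31)) {
    rec <- simulate_session(group = "sgvs", params = p, seed = seed,
                            responder = TRUE)
    in_win <- rec$time_s >= 240 & rec$time_s < 420
    bound <- (1 - p$cbf_drop_frac) * p$baseline_cbf +
      3 * p$noise_sd_frac * p$baseline_cbf
    expect_lte(min(rec$cbf_pu[in_win]), bound)
  }
})

test_that("the programmed effect is exactly the noise-free stimulation-window mean change", {
  p <- do.call(response_params, utils::modifyList(
    unclass(preset_params("sgvs")),
    list(map_drop_sd = 0, hr_drop_sd = 0, cbf_drop_sd = 0,
         noise_sd_frac = 1e-12, phase1_prob = 1, gradual_decline_prob = 1)))
  rec <- simulate_session(group = "sgvs", params = p, seed = 17,
                          responder = TRUE)
  s <- percent_change(summarize_sections(rec))
  stim <- s[s$window == "Stimulation", ]
  got <- stats::setNames(stim$pct_change, stim$channel)
  expect_equal(got[["map_mmHg"]], -100 * p$map_drop_frac, tolerance = 1e-6)
  expect_equal(got[["hr_bpm"]], -100 * p$hr_drop_frac, tolerance = 1e-6)
  expect_equal(got[["cbf_pu"]], -100 * p$cbf_drop_frac, tolerance = 1e-6)
})

test_that("cohorts have the right size, unique ids, and honest responder draws", {
  recs <- simulate_cohort(cohort_spec(n_per_group = 10,
                                      groups = c("sham", "sgvs"),
                                      master_seed = 3))
  expect_length(recs, 20)
  ids <- vapply(recs, function(r) recording_meta(r)$animal_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  groups <- vapply(recs, function(r) recording_meta(r)$group, character(1))
  expect_equal(unname(table(groups)[c("sham", "sgvs")]), c(10L, 10L),
               ignore_attr = TRUE)

  # responder_prob 1 makes every flag true
  all_resp <- simulate_cohort(
    cohort_spec(n_per_group = 5, groups = "sgvs", master_seed = 4),
    params = list(sgvs = do.call(response_params, utils::modifyList(
      unclass(preset_params("sgvs")), list(responder_prob = 1)))))
  expect_true(all(vapply(all_resp, function(r) recording_meta(r)$responder,
                         logical(1))))
})

test_that("the non-responder fraction matches the binomial rate", {
  # 2-of-10 exclusions at responder_prob 0.8; low sampling rate, the flag
  # draw does not depend on it
  recs <- simulate_cohort(cohort_spec(n_per_group = 150, groups = "sgvs",
                                      sample_rate = 1, master_seed = 99))
  frac_nonresp <- mean(!vapply(recs, function(r) recording_meta(r)$responder,
                               logical(1)))
  expect_lt(abs(frac_nonresp - 0.2), 3 * sqrt(0.8 * 0.2 / 150))
})
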