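test_that("fixed-interval schedules place onsets at baseline + k*iti", {
  s <- generate_puff_schedule(iti = 120, n_puffs = 20, baseline_length = 300)
  expect_equal(s$puff_onsets, seq(300, 2580, by = 120))
  expect_equal(s$puff_onsets[1], 300)
  expect_length(s$puff_onsets, 20)

  s4 <- generate_puff_schedule(iti = 240, n_puffs = 10, baseline_length = 300,
                               session_length = 3000)
  expect_length(s4$puff_onsets, 10)
  expect_equal(diff(range(s4$puff_onsets)), 2160)

  s1 <- generate_puff_schedule(n_puffs = 1, baseline_length = 300)
  expect_equal(s1$puff_onsets, 300)
})

test_that("schedules violating the session bounds are rejected by name", {
  expect_error(
    generate_puff_schedule(iti = 240, n_puffs = 20, baseline_length = 300,
                           session_length = 2400),
    "2460")
  expect_error(generate_puff_schedule(iti = 0, n_puffs = 5), "iti")
  expect_error(generate_puff_schedule(dose_per_puff = 0), "dose_per_puff")
})

test_that("one puff carries 0.1 mg nicotine from the 3 mg / 300 uL stock", {
  expect_equal(puff_dose_mg(), 0.1)
  expect_equal(puff_dose_mg(volume_ul = 20), 0.2)
})

test_that("craving traces follow the exponential model exactly without noise", {
  s <- generate_puff_schedule(iti = 120, n_puffs = 20, baseline_length = 300)
  tr <- generate_craving_trace(s, A = 4.2, B = 3.2, tau = 310, noise_sd = 0)
  t0 <- 300
  expect_equal(tr$rating[tr$t == t0], 4.2 + 3.2)              # zero lag
  expect_equal(tr$rating[tr$t == t0 + 310], 4.2 + 3.2 / exp(1),
               tolerance = 1e-12)                             # one decay time
  expect_true(all(tr$rating[tr$t < t0] == 4.2 + 3.2))         # pre-puff ceiling
  late <- tr$rating[tr$t > t0 + 10 * 310]
  expect_true(all(abs(late - 4.2) < 1e-3))                    # asymptote
  expect_true(all(diff(tr$t) == 1))                           # 1 s grid
})

test_that("craving traces are seed-deterministic and clipped to the scale", {
  s <- generate_puff_schedule(iti = 120, n_puffs = 20, baseline_length = 300)
  a <- generate_craving_trace(s, noise_sd = 0.5, seed = 11)
  b <- generate_craving_trace(s, noise_sd = 0.5, seed = 11)
  c <- generate_craving_trace(s, noise_sd = 0.5, seed = 12)
  expect_identical(a$rating, b$rating)
  expect_false(identical(a$rating, c$rating))
  expect_true(all(a$rating >= 0 & a$rating <= a$scale_max))

  # clipping never activates without noise when A and A+B lie in scale
  clean <- generate_craving_trace(s, noise_sd = 0, scale_max = 10)
  expect_true(all(clean$rating > 0 & clean$rating < 10))
})

test_that("ad-libitum behavior respects refractory, cap, and threshold", {
  # threshold barely below the ceiling: the model never recovers that far
  one <- generate_adlib_behavior(threshold = 7.3999, session_length = 2400)
  expect_length(one$puff_onsets, 1)

  # greedy subject: a puff every refractory period, capped at 20
  many <- generate_adlib_behavior(threshold = 4.3, refractory = 120,
                                  session_length = 2400)
  expect_length(many$puff_onsets, 20)
  expect_true(all(diff(many$puff_onsets) >= 120))

  expect_identical(generate_adlib_behavior(seed = 5)$puff_onsets,
                   generate_adlib_behavior(seed = 5)$puff_onsets)
  expect_error(generate_adlib_behavior(threshold = 9), "threshold")
})

test_that("planted single-state correlations hit their targets", {
  # complete graph: every off-diagonal pair is an edge at r = 0.8
  full <- state_plan(n_regions = 23, n_states = 1, states = list(complete_graph(23)),
                     n_windows = 100, within_edge_r = 0.8, background_r = 0.1)
  ts <- generate_roi_timeseries(full, window_length_trs = 38, seed = 42)
  rs <- vapply(cut_windows(ts), function(w) {
    cm <- cor(t(w)); mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_equal(mean(rs), 0.8, tolerance = 0.05)

  # empty graph at zero background: independence
  empty <- state_plan(n_regions = 23, n_states = 1,
                      states = list(matrix(0L, 23, 23)),
                      n_windows = 1, background_r = 0)
  ts0 <- generate_roi_timeseries(empty, window_length_trs = 380, seed = 42)
  cm <- cor(t(ts0$data))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.1)
})

test_that("ROI series have the planned shape and are seed-deterministic", {
  plan <- state_plan()
  ts <- generate_roi_timeseries(plan, window_length_trs = 38, seed = 1)
  expect_equal(dim(ts$data), c(23, 380))
  expect_equal(ts$region_labels, addiction_regions())
  ts2 <- generate_roi_timeseries(plan, window_length_trs = 38, seed = 1)
  expect_identical(ts$data, ts2$data)
  expect_false(identical(
    ts$data, generate_roi_timeseries(plan, window_length_trs = 38, seed = 2)$data))
})

test_that("state plans reject unrecoverable or hub-less structure", {
  expect_error(state_plan(within_edge_r = 0.6), "within_edge_r")
  expect_error(state_plan(background_r = 0.7), "within_edge_r")
  # a hub that no minimum dominating set contains: leaf of a star
  star <- star_graph(5)
  expect_error(
    state_plan(n_regions = 5, states = list(star), hub = 2,
               region_labels = letters[1:5]),
    "minimum dominating set")
})

test_that("file round trips preserve schedules, traces, and ROI series", {
  dir <- withr::local_tempdir()
  s <- generate_puff_schedule(iti = 240, n_puffs = 10, baseline_length = 305,
                              session_length = 3000)
  write_events_tsv(s, file.path(dir, "events.tsv"))
  ev <- read_events_tsv(file.path(dir, "events.tsv"))
  expect_equal(puff_onsets_from_events(ev), s$puff_onsets)
  expect_equal(ev$trial_type[1], "baseline")

  tr <- generate_craving_trace(s, noise_sd = 0.3, seed = 3)
  write_craving_tsv(tr, file.path(dir, "trace.tsv"))
  back <- read_craving_tsv(file.path(dir, "trace.tsv"))
  expect_equal(back$rating, tr$rating, tolerance = 1e-9)

  plan <- state_plan(n_windows = 4)
  ts <- generate_roi_timeseries(plan, seed = 9)
  write_roi_tsv(ts, file.path(dir, "roi.tsv"))
  rts <- read_roi_tsv(file.path(dir, "roi.tsv"))
  expect_equal(rts$data, ts$data, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rts$region_labels, ts$region_labels)

  write_ground_truth(plan, file.path(dir, "truth.txt"))
  lines <- readLines(file.path(dir, "truth.txt"))
  expect_match(lines[1], "^n_regions\t23$")
  expect_true(any(grepl("Anterior Cingulate Cortex", lines)))
})
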