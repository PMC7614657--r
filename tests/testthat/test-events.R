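test_that("drop onset lands on the corner of a constructed decay", {
  trace <- c(rep(100, 10), 100 * 0.85^(1:20))
  on <- detect_drop_onset(trace, search_start = 1, window_frames = 3)
  expect_true(on %in% c(9L, 10L))
  # monotonically increasing trace: no onset
  expect_true(is.na(detect_drop_onset(seq(1, 100, length.out = 40))))
  # determinism
  expect_identical(on, detect_drop_onset(trace, 1, 3))
})

test_that("drop detection latency is truncation-invariant", {
  trace <- c(rep(100, 15), 100 * 0.8^(1:25))
  full <- detect_drop_onset(trace)
  for (cut in c(20, 25, 30, 40))
    expect_identical(detect_drop_onset(trace[1:cut]), full)
})

test_that("stricter slope thresholds never move the onset earlier", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(8:20, 1)
    trace <- c(rep(100, k), 100 * runif(1, 0.7, 0.9)^(1:15)) *
      (1 + rnorm(k + 15, 0, 0.01))
    loose <- detect_drop_onset(trace, slope_max = -0.02)
    strict <- detect_drop_onset(trace, slope_max = -0.06)
    if (!is.na(loose) && !is.na(strict)) expect_gte(strict, loose)
  }
})

test_that("low-expression traces are not annotated", {
  noise <- abs(rnorm(40, 400, 80))
  expect_true(is.na(detect_drop_onset(noise, min_expression = 3000)))
})

test_that("rise onset finds the start of a persistent increase", {
  trace <- c(rep(0, 20), 5 * (1:20))
  on <- detect_rise_onset(trace)
  expect_true(abs(on - 20) <= 1)
  expect_true(is.na(detect_rise_onset(rep(3, 40))))
  # transient blip: rises then falls back below the low level -> not called
  blip <- c(rep(0, 10), 12, 14, 0, rep(0, 7), 5 * (1:20))
  on_b <- detect_rise_onset(blip)
  expect_gt(on_b, 12)
})

test_that("dual-threshold S-entry follows the hand-traced example", {
  trace <- c(0, 1, 2, 2, 2, 10, 60, 80)
  expect_identical(detect_s_entry_foci(trace, 50, 3, 4), 4L)
  expect_true(is.na(detect_s_entry_foci(c(0, 1, 5, 20, 40, 45), 50, 3, 4)))
  # never below the low threshold before the high point -> no entry
  expect_true(is.na(detect_s_entry_foci(c(10, 20, 30, 40, 80), 50, 3, 4)))
  expect_error(detect_s_entry_foci(trace, 3, 50), "low threshold")
})

test_that("S entry is detected within a frame on simulated foci traces", {
  cfg <- sim_config(n_cells_initial = 40L, seed = 31L)
  pop <- simulate_population(cfg)
  rk <- cfg$reporter_kinetics
  cc <- pop$cells
  hits <- 0; total <- 0
  for (i in seq_len(nrow(cc))) {
    tr <- pop$frames[pop$frames$cell_id == cc$cell_id[i], ]
    if (nrow(tr) < 8) next
    s_abs <- cc$s_entry_abs[i]
    if (s_abs < min(tr$time_min) + 12 || s_abs > max(tr$time_min) - 48) next
    det <- detect_s_entry_foci(tr$PCNAFOCI)
    total <- total + 1
    if (!is.na(det)) {
      det_min <- tr$time_min[det + 1]
      if (abs(det_min - s_abs) <= cfg$frame_interval_min) hits <- hits + 1
    }
  }
  expect_gt(total, 5)
  expect_gte(hits / total, 0.95)
})

test_that("drop detector recovers programmed S entries from clean traces", {
  cfg <- sim_config(n_cells_initial = 40L, seed = 32L)
  pop <- simulate_population(cfg)
  cc <- pop$cells
  errs <- c()
  for (i in seq_len(nrow(cc))) {
    tr <- pop$frames[pop$frames$cell_id == cc$cell_id[i], ]
    if (nrow(tr) < 10) next
    s_abs <- cc$s_entry_abs[i]
    if (s_abs < min(tr$time_min) + 24 || s_abs > max(tr$time_min) - 48) next
    det <- detect_drop_onset(tr$CRL4, search_start = 1)
    if (!is.na(det))
      errs <- c(errs, abs(tr$time_min[det + 1] - s_abs))
  }
  expect_gt(length(errs), 5)
  expect_lte(median(errs), cfg$frame_interval_min)
})

test_that("annotate_track dispatches detectors and falls back for S entry", {
  n <- 40
  crl4 <- c(seq(100, 15000, length.out = 25), 15000 * 0.4^(1:15))
  apcc <- c(rep(50, 22), 50 + 400 * (1:18))
  foci <- c(rep(0, 24), 30, 80, 120, rep(120, 13))
  track <- data.frame(track_id = 7L, frame = 0:(n - 1),
                      CRL4_total = crl4, APCC_total = apcc,
                      puncta_area_px = foci)
  ann <- annotate_track(track,
                        channel_map = list(crl4 = "CRL4_total",
                                           apcc = "APCC_total",
                                           foci = "puncta_area_px"),
                        frame_interval_min = 12)
  expect_equal(ann$s_entry_source, "pcna_foci")
  expect_true(abs(ann$s_entry_frame - 24) <= 1)
  expect_true(abs(ann$crl4_activation_frame - 24) <= 1)
  expect_true(abs(ann$apcc_inactivation_frame - 21) <= 1)
  expect_equal(ann$s_entry_min, ann$s_entry_frame * 12)
  # without the foci channel, the CRL4 drop is the S-entry source
  ann2 <- annotate_track(track,
                         channel_map = list(crl4 = "CRL4_total"),
                         frame_interval_min = 12)
  expect_equal(ann2$s_entry_source, "crl4_reporter")
  expect_true(is.na(ann2$apcc_inactivation_frame))
  # a flat track yields no annotations
  flat <- data.frame(track_id = 1L, frame = 0:20,
                     CRL4_total = rep(800, 21), APCC_total = rep(30, 21),
                     puncta_area_px = rep(0, 21))
  ann3 <- annotate_track(flat,
                         channel_map = list(crl4 = "CRL4_total",
                                            apcc = "APCC_total",
                                            foci = "puncta_area_px"),
                         params = list(drop = list(min_expression = 3000)))
  expect_true(is.na(ann3$s_entry_frame))
  expect_true(is.na(ann3$apcc_inactivation_frame))
})
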