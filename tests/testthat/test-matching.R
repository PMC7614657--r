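test_that("translation registration recovers programmed offsets", {
  cfg <- sim_config(field_size_px = c(256L, 256L), n_frames = 8L,
                    n_cells_initial = 15L, seed = 41L)
  pop <- simulate_population(cfg)
  rf <- rtqibc:::render_live_frame(pop, cfg, 7)
  # identical images, ratio 1
  expect_equal(register_translation(rf$images$H2B, rf$images$H2B),
               c(dx = 0, dy = 0))
  # rendered fixed snapshot with a known offset
  cfg1 <- cfg; cfg1$fixed <- list(magnification_ratio = 1,
                                  offset_px = c(17, -9))
  fx <- render_fixed_snapshot(pop, cfg1)
  off <- register_translation(fx$images$DNA, rf$images$H2B)
  expect_equal(off, c(dx = 17, dy = -9))
  # ratio 2, both strategies, within 1 px
  cfg2 <- cfg; cfg2$fixed <- list(magnification_ratio = 2,
                                  offset_px = c(10, 4))
  fx2 <- render_fixed_snapshot(pop, cfg2)
  for (strat in c("upsample_live", "bin_fixed")) {
    o2 <- register_translation(fx2$images$DNA, rf$images$H2B,
                               magnification_ratio = 2, strategy = strat)
    expect_lte(abs(o2[["dx"]] - 10), 1)
    expect_lte(abs(o2[["dy"]] - 4), 1)
  }
  # registration of unrelated noise fails
  set.seed(1)
  expect_error(register_translation(matrix(rnorm(256^2), 256, 256),
                                    matrix(rnorm(256^2), 256, 256)),
               "registration failed")
})

test_that("offset recovery holds across magnitudes with noise", {
  cfg <- sim_config(field_size_px = c(256L, 256L), n_frames = 5L,
                    n_cells_initial = 15L, seed = 43L)
  pop <- simulate_population(cfg)
  rf <- rtqibc:::render_live_frame(pop, cfg, 4)
  for (off_true in list(c(0, 0), c(50, -50), c(-31, 12))) {
    cfg1 <- cfg; cfg1$fixed <- list(magnification_ratio = 1,
                                    offset_px = off_true)
    fx <- render_fixed_snapshot(pop, cfg1)
    img <- rtqibc:::with_seed(7,
      rtqibc:::apply_camera_model_fixed(fx$images$DNA, cfg1, noise = TRUE))
    off <- register_translation(img, rf$images$H2B)
    expect_lte(abs(off[["dx"]] - off_true[1]), 1)
    expect_lte(abs(off[["dy"]] - off_true[2]), 1)
  }
})

test_that("fixed cells match their nearest live neighbours one-to-one", {
  set.seed(9)
  live <- data.frame(x = runif(60, 10, 300), y = runif(60, 10, 300))
  fixed <- data.frame(x = 2 * live$x + 5, y = 2 * live$y - 3)
  m <- match_fixed_to_live(fixed, live, c(dx = 5, dy = -3),
                           magnification_ratio = 2, max_dist_px = 8)
  expect_equal(nrow(m), 60)
  expect_equal(m$fixed, m$live)
  expect_equal(attr(m, "n_dropped"), 0)
  # empty fixed set
  m0 <- match_fixed_to_live(fixed[0, ], live, c(dx = 0, dy = 0))
  expect_equal(nrow(m0), 0)
  # a far-away fixed cell is dropped
  far <- rbind(fixed, data.frame(x = 1000, y = 1000))
  m1 <- match_fixed_to_live(far, live, c(dx = 5, dy = -3), 2, 8)
  expect_equal(attr(m1, "n_dropped"), 1)
  # one live cell never receives two fixed cells
  dup <- rbind(fixed, fixed + 0.5)
  m2 <- match_fixed_to_live(dup, live, c(dx = 5, dy = -3), 2, 8)
  expect_false(any(duplicated(m2$live)))
})

test_that("acquisition offsets follow the cycle position", {
  sched <- c("s1", "s2", "s3", "s4", "s5", "s6")
  expect_equal(assign_acquisition_times("s1", sched, 12), 0)
  expect_equal(assign_acquisition_times("s4", sched, 12), 6)
  offs <- assign_acquisition_times(sched, sched, 12)
  expect_true(all(diff(offs) > 0))
  expect_error(assign_acquisition_times("nope", sched, 12), "unknown")
  df_sched <- data.frame(site_id = sched, position = 0:5)
  expect_equal(assign_acquisition_times("s3", df_sched, 12), 4)
})

test_that("staining rounds align to the first round", {
  cfg <- sim_config(field_size_px = c(192L, 192L), n_frames = 5L,
                    n_cells_initial = 10L, seed = 47L)
  pop <- simulate_population(cfg)
  base <- render_fixed_snapshot(pop, cfg)$images$DNA
  shift_im <- function(im, dy, dx) {
    out <- matrix(median(im), nrow(im), ncol(im))
    src_r <- seq_len(nrow(im) - abs(dy)); src_c <- seq_len(ncol(im) - abs(dx))
    out[src_r + max(dy, 0), src_c + max(dx, 0)] <-
      im[src_r + max(-dy, 0), src_c + max(-dx, 0)]
    out
  }
  rounds <- list(base, shift_im(base, 6, -11), shift_im(base, -4, 3))
  al <- align_staining_rounds(rounds)
  expect_equal(al$dx, c(0, -11, 3))
  expect_equal(al$dy, c(0, 6, -4))
  # an information-free round returns NA offsets, others unaffected
  rounds_bad <- list(base, matrix(1, 384, 384), shift_im(base, 2, 2))
  al2 <- align_staining_rounds(rounds_bad)
  expect_true(is.na(al2$dx[2]))
  expect_equal(al2$dx[3], 2)
  expect_error(align_staining_rounds(rounds[1]), "rounds")
})

test_that("records join fixed measurements to live events with derived times", {
  fixed_table <- data.frame(label = 1:3, EDU_total = c(5, 6, 7),
                            x = c(10, 20, 30), y = c(10, 20, 30))
  tracks <- structure(list(
    tracks = data.frame(track_id = 1:3, parent_track_id = NA_integer_,
                        start_frame = 0L, end_frame = 10L,
                        division_frame = NA_integer_,
                        end_reason = "movie_end"),
    observations = data.frame(track_id = 1:3, frame = 10L,
                              x = c(10, 20, 30), y = c(10, 20, 30),
                              total = 1)), class = "cell_tracks")
  ann <- data.frame(track_id = 1:3,
                    anaphase_min = c(0, NA, 12),
                    apcc_inactivation_min = c(60, NA, NA),
                    s_entry_min = c(84, NA, 96),
                    s_entry_frame = c(7L, NA, 8L),
                    s_entry_source = c("pcna_foci", NA, "crl4_reporter"))
  assignment <- data.frame(fixed = 1:3, live = 1:3, dist_px = 0.5)
  live_table <- tracks$observations
  rec <- assemble_records(fixed_table, tracks, ann, assignment, live_table,
                          movie_end_min = 120, site_offset_min = 6)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$time_since_s_entry_min, c(126 - 84, NA, 126 - 96))
  expect_equal(rec$time_since_anaphase_min, c(126, NA, 114))
  expect_true(is.na(rec$time_since_apcc_inactivation_min[3]))
  expect_equal(rec$fixed_EDU_total, c(5, 6, 7))
  # live side is lossless: each track at most once
  expect_false(any(duplicated(rec$track_id)))
  bad <- assignment; bad$fixed[1] <- 99
  expect_error(assemble_records(fixed_table, tracks, ann, bad, live_table,
                                120), "unknown")
})
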