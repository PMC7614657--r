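test_that("identical frames link one-to-one; shifts within range link fully", {
  a <- obs_frame(0, x = c(10, 40, 80), y = c(15, 50, 20),
                 total = c(100, 120, 90))
  lk <- link_frames(a, a, max_dist_px = 15)
  expect_equal(lk$matches$prev, lk$matches$curr)
  expect_false(any(lk$matches$flagged))
  b <- a; b$x <- a$x + 3; b$frame <- 1
  lk2 <- link_frames(a, b, max_dist_px = 15)
  expect_equal(nrow(lk2$matches), 3)
  expect_equal(lk2$matches$prev, lk2$matches$curr)
  # beyond max_dist nothing links
  c2 <- a; c2$x <- a$x + 30
  lk3 <- link_frames(a, c2, max_dist_px = 15)
  expect_equal(nrow(lk3$matches), 0)
  expect_equal(lk3$unmatched_prev, 1:3)
})

test_that("a segmentation merge is flagged and repaired from two predecessors", {
  prev <- obs_frame(0, x = c(20, 28), y = c(20, 20), total = c(100, 110))
  curr <- obs_frame(1, x = 24, y = 20, total = 208)
  lk <- link_frames(prev, curr, max_dist_px = 10)
  expect_true(any(lk$matches$flagged))
  expect_gt(lk$matches$signal_ratio[1], 1.8)
  rp <- repair_merge_split(lk, prev, curr, signal_tolerance = 0.3,
                           max_dist_px = 10)
  expect_equal(nrow(rp$resolved), 2)
  expect_equal(nrow(rp$curr_repaired), 2)
  expect_equal(sum(rp$curr_repaired$total), 208)
  expect_equal(rp$curr_repaired$total[1] / rp$curr_repaired$total[2],
               100 / 110, tolerance = 1e-9)
  # no flags -> identity
  lk_ok <- link_frames(prev, prev, max_dist_px = 10)
  rp_ok <- repair_merge_split(lk_ok, prev, prev)
  expect_equal(nrow(rp_ok$resolved), 0)
  expect_identical(rp_ok$curr_repaired, prev)
})

test_that("one-frame merges leave both tracks unbroken in build_tracks", {
  frames <- list(
    obs_frame(0, x = c(20, 30), y = c(20, 20), total = c(100, 110)),
    obs_frame(1, x = c(21, 29), y = c(20, 20), total = c(101, 109)),
    obs_frame(2, x = 25, y = 20, total = 209),                 # merged
    obs_frame(3, x = c(21, 29), y = c(20, 20), total = c(99, 111)),
    obs_frame(4, x = c(20, 30), y = c(20, 20), total = c(100, 110))
  )
  tk <- build_tracks(frames, params = list(max_dist_px = 10))
  expect_equal(nrow(tk$tracks), 2)
  expect_true(all(tk$tracks$end_reason == "movie_end"))
  expect_true(all(table(tk$observations$track_id) == 5))
})

test_that("a persistent merge ends the weaker track as lost", {
  frames <- c(
    list(obs_frame(0, x = c(20, 30), y = c(20, 20), total = c(100, 140))),
    lapply(1:6, function(f) obs_frame(f, x = 25, y = 20, total = 240))
  )
  tk <- build_tracks(frames, params = list(max_dist_px = 12, k_frames = 3))
  expect_equal(nrow(tk$tracks), 2)
  expect_equal(sort(tk$tracks$end_reason), c("lost", "movie_end"))
  # the weaker member of the unresolved merge is the one lost; the
  # stronger continues with its share of the merged signal
  lost <- tk$tracks[tk$tracks$end_reason == "lost", ]
  surv <- tk$tracks[tk$tracks$end_reason == "movie_end", ]
  obs_s <- tk$observations[tk$observations$track_id == surv$track_id, ]
  obs_l <- tk$observations[tk$observations$track_id == lost$track_id, ]
  expect_equal(surv$end_frame, 6)
  expect_gt(obs_s$total[nrow(obs_s)], obs_l$total[nrow(obs_l)])
  expect_equal(obs_s$total[nrow(obs_s)] + obs_l$total[nrow(obs_l)], 240,
               tolerance = 1e-9)
})

test_that("division requires conserved summed signal", {
  parent <- obs_frame(5, x = 50, y = 50, total = 100)
  ok <- obs_frame(6, x = c(45, 55), y = c(50, 50), total = c(48, 51))
  bad <- obs_frame(6, x = c(45, 55), y = c(50, 50), total = c(30, 30))
  tk_ok <- build_tracks(list(parent, ok),
                        params = list(max_dist_px = 4, vicinity_px = 10,
                                      division_tolerance = 0.2))
  div <- tk_ok$tracks[tk_ok$tracks$end_reason == "divided", ]
  expect_equal(nrow(div), 1)
  kids <- tk_ok$tracks[!is.na(tk_ok$tracks$parent_track_id), ]
  expect_equal(nrow(kids), 2)
  expect_equal(kids$start_frame, rep(div$division_frame + 1L, 2))
  tk_bad <- build_tracks(list(parent, bad),
                         params = list(max_dist_px = 4, vicinity_px = 10,
                                       division_tolerance = 0.2))
  expect_equal(sum(tk_bad$tracks$end_reason == "divided"), 0)
  # detect_mitosis re-derives the same event from the built tracks
  ev <- detect_mitosis(tk_ok, vicinity_px = 10, signal_tolerance = 0.2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$division_frame, 5)
})

test_that("degenerate inputs produce empty or single-track results", {
  expect_equal(nrow(build_tracks(list())$tracks), 0)
  one <- lapply(0:9, function(f) obs_frame(f, x = 50 + f, y = 50, total = 100))
  tk <- build_tracks(one)
  expect_equal(nrow(tk$tracks), 1)
  expect_equal(tk$tracks$end_reason, "movie_end")
  expect_equal(nrow(tk$observations), 10)
})

test_that("tracking the synthetic benchmark: links >= 99%, divisions found", {
  # observation-level benchmark built from the generator's ground truth
  cfg <- sim_config(n_cells_initial = 40L, seed = 17L)
  pop <- simulate_population(cfg)
  fr <- pop$frames
  frames <- lapply(sort(unique(fr$frame)), function(f) {
    s <- fr[fr$frame == f, ]
    data.frame(frame = f, label = seq_len(nrow(s)), x = s$x, y = s$y,
               total = s$H2B, area_px = s$area_px, cell_id = s$cell_id)
  })
  tk <- build_tracks(frames, params = list(
    max_dist_px = max(10, 3 * cfg$motion_sigma_px_per_frame),
    vicinity_px = 4 * mean(cfg$nucleus_radius_um) / cfg$pixel_size_um))
  obs <- tk$observations
  # link accuracy: consecutive observations of a track are the same cell
  obs <- obs[order(obs$track_id, obs$frame), ]
  same_track <- diff(obs$track_id) == 0
  good_link <- diff(obs$cell_id) == 0
  acc <- sum(same_track & good_link) / sum(same_track)
  expect_gte(acc, 0.99)
  # divisions: every true division inside the movie detected within 1 frame,
  # no division event without a matching true division
  true_div <- pop$cells[!is.na(pop$cells$division_time), ]
  det_div <- tk$tracks[tk$tracks$end_reason == "divided", ]
  det_cells <- obs$cell_id[match(det_div$track_id, obs$track_id)]
  # map each detected division to the cell the parent track ends on
  last_cells <- vapply(det_div$track_id, function(tid) {
    o <- obs[obs$track_id == tid, ]
    o$cell_id[which.max(o$frame)]
  }, 0)
  det_frames <- det_div$division_frame
  true_frames <- floor(true_div$division_time / cfg$frame_interval_min)
  hit <- vapply(seq_len(nrow(true_div)), function(i) {
    j <- which(last_cells == true_div$cell_id[i])
    length(j) > 0 && any(abs(det_frames[j] - true_frames[i]) <= 1)
  }, TRUE)
  expect_gte(mean(hit), 0.95)
  # false positives: detected parents that never truly divide
  fp <- sum(!last_cells %in% true_div$cell_id)
  expect_equal(fp, 0)
  expect_gte(nrow(true_div), 20)
})

test_that("track partition and lineage invariants hold on the benchmark", {
  cfg <- small_config(seed = 23L)
  pop <- simulate_population(cfg)
  fr <- pop$frames
  frames <- lapply(sort(unique(fr$frame)), function(f) {
    s <- fr[fr$frame == f, ]
    data.frame(frame = f, label = seq_len(nrow(s)), x = s$x, y = s$y,
               total = s$H2B, area_px = s$area_px)
  })
  tk <- build_tracks(frames)
  obs <- tk$observations
  # partition: every observation in exactly one track, no skipped frames
  expect_equal(nrow(obs), nrow(fr))
  for (tid in tk$tracks$track_id) {
    f <- sort(obs$frame[obs$track_id == tid])
    expect_true(all(diff(f) == 1))
  }
  # lineage: daughters start the frame after the parent's division
  kids <- tk$tracks[!is.na(tk$tracks$parent_track_id), ]
  if (nrow(kids)) {
    pf <- tk$tracks$division_frame[match(kids$parent_track_id,
                                         tk$tracks$track_id)]
    expect_equal(kids$start_frame, pf + 1L)
    expect_true(all(table(kids$parent_track_id) == 2))
  }
})
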