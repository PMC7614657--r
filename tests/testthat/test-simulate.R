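test_that("simulation is bitwise deterministic given the seed", {
  cfg <- small_config(seed = 1L)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$frames, p2$frames)
  p3 <- simulate_population(small_config(seed = 2L))
  expect_false(identical(p1$frames, p3$frames))
})

test_that("generated populations satisfy the event-ordering invariants", {
  pop <- simulate_population(small_config(seed = 3L))
  cc <- pop$cells
  expect_true(all(cc$birth_abs < cc$apcc_abs))
  expect_true(all(cc$apcc_abs < cc$s_entry_abs))
  both <- !is.na(cc$s_entry_time) & !is.na(cc$cdt1_fully_degraded_time)
  expect_true(all(cc$cdt1_fully_degraded_time[both] >= cc$s_entry_time[both]))
  tr_cols <- c("CRL4", "APCC", "CDT1IF", "GMNNIF", "PCNAFOCI")
  expect_true(all(as.matrix(pop$frames[tr_cols]) >= 0))
  # lineage: daughters exist and share the parent's division time as birth
  kids <- cc[!is.na(cc$parent_id), ]
  expect_gt(nrow(kids), 0)
  expect_equal(kids$birth_abs,
               cc$division_abs[match(kids$parent_id, cc$cell_id)])
})

test_that("a programmed S entry puts the CRL4 peak at the programmed frame", {
  cfg <- sim_config(field_size_px = c(128L, 128L), n_frames = 60L,
                    n_cells_initial = 1L, seed = 9L)
  prog <- data.frame(birth_time = -20, g1 = 500, s = 540, g2m = 300,
                     x = 60, y = 60)
  # S entry at -20 + 500 = 480 min = frame 40
  pop <- simulate_population(cfg, programmed = prog)
  tr <- pop$frames[pop$frames$cell_id == 1, ]
  expect_equal(tr$frame[which.max(tr$CRL4)], 40)
  post <- tr$CRL4[tr$frame %in% 40:50]
  expect_true(all(diff(post) < 0))
})

test_that("CDT1-IF reaches the degraded gate within 33 min of S entry", {
  cfg <- small_config()
  rk <- cfg$reporter_kinetics
  # analytic decay: level after t minutes is 2^(-t / half-time)
  expect_lt(2^(-33 / rk$cdt1_if_half_min), rk$degraded_gate_frac)
  # and on generated cells: evaluate the trace 33 min after S entry
  pop <- simulate_population(small_config(seed = 4L))
  cc <- pop$cells
  lvl <- rtqibc:::cdt1_if_trace(cc$s_entry_abs + 33, cc$s_entry_abs,
                                cc$s_end_abs, cc$division_abs,
                                rep(1, nrow(cc)), rk$cdt1_if_half_min)
  expect_gte(mean(lvl < rk$degraded_gate_frac), 0.9)
})

test_that("rendering conserves intensity within and across frames", {
  cfg <- sim_config(field_size_px = c(128L, 128L), n_frames = 10L,
                    n_cells_initial = 1L, seed = 2L,
                    camera = list(offset = 0, illumination = "flat",
                                  read_noise_sd = 0, shot_scale = 0,
                                  bleedthrough = list(), background_au = 0))
  prog <- data.frame(birth_time = -100, g1 = 700, s = 540, g2m = 300,
                     x = 60, y = 60)
  pop <- simulate_population(cfg, programmed = prog)
  mv <- render_movie(pop, cfg, channels = "H2B")
  tots <- vapply(mv$stacks$H2B, sum, 0)
  expect_lt(max(abs(tots / tots[1] - 1)), 0.001)
})

test_that("division renders as two nearby components whose signal sums", {
  cfg <- sim_config(field_size_px = c(160L, 160L), n_frames = 20L,
                    n_cells_initial = 1L, seed = 13L,
                    camera = list(offset = 0, illumination = "flat",
                                  read_noise_sd = 0, shot_scale = 0,
                                  bleedthrough = list(), background_au = 0))
  # division at 60 min = just before frame 6
  prog <- data.frame(birth_time = -1320, g1 = 540, s = 540, g2m = 300,
                     x = 80, y = 80)
  pop <- simulate_population(cfg, programmed = prog)
  k <- ceiling(pop$cells$division_abs[1] / cfg$frame_interval_min)
  mv <- render_movie(pop, cfg, channels = "H2B")
  before <- mv$stacks$H2B[[k]]      # frame k-1 (parent's last)
  after <- mv$stacks$H2B[[k + 1L]]  # frame k (daughters)
  lab <- EBImage::bwlabel(after > 0.4 * max(after))
  expect_equal(max(lab), 2)
  expect_lt(abs(sum(after) / sum(before) - 1), 0.05)
  cen_before <- pop$frames[pop$frames$cell_id == 1, ]
  cen_before <- cen_before[nrow(cen_before), c("x", "y")]
  cen_after <- rtqibc:::label_centroids(as.matrix(lab))
  expect_true(all(sqrt((cen_after$x - cen_before$x)^2 +
                         (cen_after$y - cen_before$y)^2) < 20))
})

test_that("PCNA foci are rendered only inside S-phase nuclei", {
  cfg <- sim_config(field_size_px = c(128L, 128L), n_frames = 10L,
                    n_cells_initial = 1L, seed = 3L,
                    camera = list(offset = 0, illumination = "flat",
                                  read_noise_sd = 0, shot_scale = 0,
                                  bleedthrough = list(), background_au = 0))
  prog <- data.frame(birth_time = -600, g1 = 540, s = 540, g2m = 300,
                     x = 60, y = 60)  # in S for the whole short movie
  pop <- simulate_population(cfg, programmed = prog)
  rf <- rtqibc:::render_live_frame(pop, cfg, 8)
  foci_px <- rf$images$PCNAFOCI > 100   # foci amplitude >> blob
  expect_gt(sum(foci_px), 0)
  expect_true(all(rf$mask[foci_px] > 0))
})

test_that("camera model follows offset + profile x signal (+ bleedthrough)", {
  cfg <- sim_config(field_size_px = c(64L, 64L), seed = 1L,
                    n_cells_initial = 2L,
                    camera = list(offset = 100, illumination = "flat",
                                  read_noise_sd = 0, shot_scale = 0,
                                  bleedthrough = list(A_B = 0.1),
                                  background_au = 0))
  S <- matrix(40, 64, 64)
  expect_equal(apply_camera_model(S, cfg, noise = FALSE),
               matrix(140, 64, 64))
  # non-flat profile: output is offset + profile * signal pixel by pixel
  cfg2 <- cfg; cfg2$camera$illumination <- "gaussian"
  prof <- rtqibc:::illumination_field(cfg2)
  out2 <- apply_camera_model(S, cfg2, noise = FALSE)
  expect_equal(out2, 100 + prof * 40, tolerance = 1e-12)
  # bleedthrough: A = 200 bleeds 0.1 into B with zero B signal
  A <- matrix(200, 64, 64); B <- matrix(0, 64, 64)
  outB <- apply_camera_model(B, cfg, channel = "B", sources = list(A = A),
                             noise = FALSE)
  expect_equal(outB, matrix(100 + 20, 64, 64))
})

test_that("fixed snapshot centroids follow ratio x live + offset", {
  cfg0 <- sim_config(field_size_px = c(160L, 160L), n_frames = 10L,
                     n_cells_initial = 5L, seed = 21L,
                     fixed = list(magnification_ratio = 1,
                                  offset_px = c(0L, 0L)))
  pop <- simulate_population(cfg0)
  last <- pop$frames[pop$frames$frame == 9, ]
  # identity
  fx0 <- render_fixed_snapshot(pop, cfg0)
  expect_equal(fx0$truth$x, last$x[match(fx0$truth$cell_id, last$cell_id)],
               tolerance = 1e-12)
  # pure translation
  cfg1 <- cfg0; cfg1$fixed <- list(magnification_ratio = 1,
                                   offset_px = c(17, -9))
  fx1 <- render_fixed_snapshot(pop, cfg1)
  expect_equal(fx1$truth$x - fx0$truth$x, rep(17, nrow(fx1$truth)))
  expect_equal(fx1$truth$y - fx0$truth$y, rep(-9, nrow(fx1$truth)))
  # magnification: fixed = 2 * live + offset
  cfg2 <- cfg0; cfg2$fixed <- list(magnification_ratio = 2,
                                   offset_px = c(10, 4))
  fx2 <- render_fixed_snapshot(pop, cfg2)
  expect_equal(fx2$truth$x, 2 * fx0$truth$x + 10, tolerance = 1e-12)
  expect_equal(fx2$truth$y, 2 * fx0$truth$y + 4, tolerance = 1e-12)
  expect_error({
    cfg3 <- cfg0; cfg3$fixed$magnification_ratio <- 0.5
    render_fixed_snapshot(pop, cfg3)
  }, "ratio")
})
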