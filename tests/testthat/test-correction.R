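make_profile_stack <- function(n_images = 12, size = 96L, offset = 100,
                               bg = 30, seed = 1L) {
  cfg <- sim_config(field_size_px = c(size, size), seed = seed,
                    n_cells_initial = 2L,
                    camera = list(offset = offset, illumination = "gaussian",
                                  illumination_amplitude = 0.3,
                                  read_noise_sd = 0, shot_scale = 0,
                                  bleedthrough = list(), background_au = bg))
  prof <- rtqibc:::illumination_field(cfg)
  imgs <- list(); masks <- list()
  set.seed(seed)
  for (i in seq_len(n_images)) {
    # a few nuclei at random positions on uniform autofluorescence
    sig <- matrix(bg, size, size)
    mk <- matrix(0L, size, size)
    for (j in 1:3) {
      x <- runif(1, 12, size - 13); y <- runif(1, 12, size - 13)
      sig <- rtqibc:::add_blob(sig, x, y, 8, 15000)
      xs <- matrix(rep(0:(size - 1), each = size), size, size)
      ys <- matrix(rep(0:(size - 1), times = size), size, size)
      mk[(xs - x)^2 + (ys - y)^2 <= 64] <- j
    }
    imgs[[i]] <- offset + prof * sig
    masks[[i]] <- mk
  }
  list(images = imgs, masks = masks, profile = prof, offset = offset, bg = bg)
}

test_that("illumination profile is recovered from background pixels", {
  st <- make_profile_stack()
  est <- estimate_illumination(st$images, st$masks, camera_offset = st$offset)
  expect_s3_class(est, "illumination_profile")
  expect_equal(mean(est$profile), 1, tolerance = 1e-9)
  rel <- est$profile / (st$profile / mean(st$profile))
  expect_lt(max(abs(rel - 1)), 0.01)
})

test_that("uniform background yields a unit profile; degenerate inputs fail", {
  size <- 96L
  flat <- replicate(12, matrix(150, size, size), simplify = FALSE)
  masks <- replicate(12, matrix(0L, size, size), simplify = FALSE)
  est <- estimate_illumination(flat, masks, camera_offset = 100)
  expect_lt(max(abs(est$profile - 1)), 1e-9)
  # offset-only images (zero signal after offset removal) are rejected
  dark <- replicate(12, matrix(100, size, size), simplify = FALSE)
  expect_error(estimate_illumination(dark, masks, camera_offset = 100),
               "no background signal")
  expect_error(estimate_illumination(flat[1:5], masks[1:5]), ">= 10")
  # almost-everywhere masked: insufficient coverage
  full <- replicate(12, matrix(1L, size, size), simplify = FALSE)
  expect_error(estimate_illumination(flat, full, camera_offset = 100),
               "coverage")
})

test_that("profile estimate is stable across image subsets", {
  st <- make_profile_stack(n_images = 24)
  e1 <- estimate_illumination(st$images[1:20], st$masks[1:20],
                              camera_offset = st$offset)
  e2 <- estimate_illumination(st$images[5:24], st$masks[5:24],
                              camera_offset = st$offset)
  expect_lt(max(abs(e1$profile / e2$profile - 1)), 0.01)
})

test_that("flat-field correction inverts the camera mapping", {
  # image = 100 + 1 * S -> S
  S <- matrix(runif(64 * 64, 0, 500), 64, 64)
  flat <- structure(list(profile = matrix(1, 64, 64), camera_offset = 100,
                         source = "provided"), class = "illumination_profile")
  expect_equal(flatfield_correct(100 + S, flat), S)
  # pixelwise: 120 at profile 0.5, offset 100 -> 40
  p <- structure(list(profile = matrix(0.5, 1, 1), camera_offset = 100,
                      source = "provided"), class = "illumination_profile")
  expect_equal(flatfield_correct(matrix(120, 1, 1), p), matrix(40, 1, 1))
  expect_error(flatfield_correct(matrix(0, 2, 2), p), "shape")
  # end-to-end synthetic round trip, noise off: machine precision
  cfg <- sim_config(field_size_px = c(96L, 96L), n_frames = 5L,
                    n_cells_initial = 3L, seed = 7L)
  pop <- simulate_population(cfg)
  rf <- rtqibc:::render_live_frame(pop, cfg, 2)
  raw <- apply_camera_model(rf$images$H2B, cfg, noise = FALSE)
  prof <- structure(list(profile = rtqibc:::illumination_field(cfg),
                         camera_offset = cfg$camera$offset,
                         source = "provided"), class = "illumination_profile")
  expect_equal(flatfield_correct(raw, prof), rf$images$H2B,
               tolerance = 1e-12)
})

test_that("bleedthrough correction is linear, clipped, and idempotent at 0", {
  A <- matrix(200, 8, 8); B <- matrix(20, 8, 8)
  expect_equal(correct_bleedthrough(B, A, 0), B)
  expect_equal(correct_bleedthrough(B, A, 0.1), matrix(0, 8, 8))  # clipped
  expect_equal(correct_bleedthrough(A, B, 0.1), A - 2)
  expect_error(correct_bleedthrough(B, A, 1), "coefficient")
  expect_error(correct_bleedthrough(B, matrix(0, 4, 4), 0.1), "shape")
  # synthetic contaminated channel round trip (noise off)
  cfg <- sim_config(field_size_px = c(96L, 96L), n_frames = 5L,
                    n_cells_initial = 3L, seed = 8L,
                    camera = list(offset = 100, illumination = "flat",
                                  read_noise_sd = 0, shot_scale = 0,
                                  bleedthrough = list(H2B_CRL4 = 0.1),
                                  background_au = 10))
  pop <- simulate_population(cfg)
  rf <- rtqibc:::render_live_frame(pop, cfg, 1)
  rawB <- apply_camera_model(rf$images$CRL4, cfg, channel = "CRL4",
                             sources = list(H2B = rf$images$H2B),
                             noise = FALSE)
  corrB <- correct_bleedthrough(rawB - 100, rf$images$H2B, 0.1)
  expect_equal(corrB, rf$images$CRL4, tolerance = 1e-10)
})
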