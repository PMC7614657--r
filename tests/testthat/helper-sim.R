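# Shared fixture builders for the test suite. Everything is generated in
# code; no stored images.

# A small, fast configuration for unit tests.
small_config <- function(seed = 5L, ...) {
  sim_config(field_size_px = c(320L, 320L), n_frames = 30L,
             n_cells_initial = 12L, seed = seed, ...)
}

# Printed Hill parameter sets used throughout (a.u.): EdU ceiling anchored
# at 22 so that fold-inhibition equals edu_max/edu_min.
hp_sictrl <- function() hill_params(22, 22 / 22.0, 10.2, 4.2)
hp_sigmnn <- function() hill_params(22, 22 / 23.0, 7.7, 1.8)
hp_dmso <- function() hill_params(22, 22 / 25.7, 5.49, 4.2)

# Render one corrected live frame of a population (noise optional).
corrected_frame <- function(pop, cfg, f, noise = TRUE, seed = 42L) {
  rf <- rtqibc:::render_live_frame(pop, cfg, f)
  prof <- rtqibc:::illumination_field(cfg)
  lapply(rf$images, function(img) {
    raw <- rtqibc:::with_seed(seed + f,
                              apply_camera_model(img, cfg, noise = noise))
    pmax((raw - cfg$camera$offset) / prof, 0)
  })
}

# A rendered, centred synthetic nucleus in an otherwise empty field.
single_nucleus_image <- function(size = 96L, radius_px = 9, total = 20000,
                                 background = 0) {
  img <- matrix(background, size, size)
  rtqibc:::add_blob(img, (size - 1) / 2, (size - 1) / 2, radius_px, total)
}

# Binary mask of two overlapping discs (figure-eight), for splitting tests.
figure_eight_mask <- function(size = 80L, r = 12, sep = 18) {
  cx1 <- (size - 1) / 2 - sep / 2; cx2 <- (size - 1) / 2 + sep / 2
  cy <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1), each = size), size, size)
  ys <- matrix(rep(0:(size - 1), times = size), size, size)
  m <- ((xs - cx1)^2 + (ys - cy)^2 <= r^2) |
    ((xs - cx2)^2 + (ys - cy)^2 <= r^2)
  matrix(as.integer(m), size, size)
}

# Observation frames for tracking tests: cells as rows of (x, y, total).
obs_frame <- function(frame, x, y, total, ...) {
  data.frame(frame = frame, label = seq_along(x), x = x, y = y,
             total = total, area_px = 150, ...)
}
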