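# End-to-end RT-QIBC pipeline on synthetic plates: render/correct/segment/
# quantify each live frame, track, annotate events, process the fixed
# snapshot, register, match, and assemble event-aligned records.

#' Quantify one corrected live frame
#'
#' Segments nuclei from the H2B channel, estimates per-channel backgrounds,
#' and measures per-cell totals plus PCNA puncta area.
#'
#' @param images named list of flat-field-corrected channel images
#'   (must include `H2B`; optionally `CRL4`, `APCC`, `PCNAFOCI`).
#' @param frame 0-based frame index to record.
#' @param config a [sim_config()] (for diameter range and pixel size).
#' @param puncta_threshold top-hat threshold for the foci channel (counts).
#' @return data frame of per-cell observations for this frame.
#' @export
quantify_live_frame <- function(images, frame, config, puncta_threshold = 50) {
  cfg <- config
  d_um <- sort(cfg$nucleus_radius_um) * 2
  mask <- detect_nuclei_log(images$H2B, diameter_range_um = d_um,
                            pixel_size_um = cfg$pixel_size_um)
  if (max(mask) == 0)
    return(data.frame(frame = integer(), label = integer(), x = numeric(),
                      y = numeric(), total = numeric(), area_px = numeric()))
  # one background region (dilated-mask complement) serves all channels
  r_px <- round(7.8 / cfg$pixel_size_um)
  outside <- !dilate_mask(mask > 0, r_px)
  idx <- which(mask > 0)
  lab <- factor(mask[idx])
  labels <- as.integer(levels(lab))
  area <- tabulate(lab)
  rr <- ((idx - 1L) %% nrow(mask))        # 0-based y
  cc <- ((idx - 1L) %/% nrow(mask))       # 0-based x
  bg_tot <- function(img) {
    bg <- stats::quantile(img[outside], 0.25, names = FALSE)
    as.numeric(tapply(img[idx], lab, sum)) - bg * area
  }
  out <- data.frame(frame = frame, label = labels,
                    x = as.numeric(tapply(cc, lab, mean)),
                    y = as.numeric(tapply(rr, lab, mean)),
                    total = bg_tot(images$H2B), area_px = area)
  for (ch in intersect(c("CRL4", "APCC"), names(images)))
    out[[paste0(ch, "_total")]] <- bg_tot(images[[ch]])
  if ("PCNAFOCI" %in% names(images)) {
    pa <- measure_puncta_area(images$PCNAFOCI, mask, tophat_radius_px = 2,
                              thresholds = puncta_threshold)
    out$puncta_area_px <- pa$puncta_area_px[match(out$label, pa$label)]
  }
  out
}

#' Run the full RT-QIBC pipeline on one synthetic site
#'
#' Simulates a population, streams rendered live frames through the camera
#' model, flat-field correction, segmentation, and quantification; tracks
#' nuclei with mitosis detection; annotates cell-cycle events on each track;
#' renders and processes the end-point fixed snapshot; registers fixed to
#' live, matches cells, and assembles RT-QIBC records.
#'
#' @param config a [sim_config()].
#' @param site_id,well_id identifiers for the records.
#' @param site_offset_min acquisition-time offset of this site (minutes).
#' @param noise apply camera noise (disable for exactness checks).
#' @return list: `records` (RT-QIBC records), `tracks`, `annotations`,
#'   `population` (ground truth), `fixed_truth`, `offset` (registration),
#'   `match` (fixed-to-live assignment), `live_last` (last-frame live table).
#' @export
run_rtqibc_site <- function(config, site_id = 1L, well_id = 1L,
                            site_offset_min = 0, noise = TRUE) {
  cfg <- validate_sim_config(config)
  pop <- simulate_population(cfg)
  prof <- illumination_field(cfg)
  offset_cam <- cfg$camera$offset %||% 0
  frames_obs <- vector("list", cfg$n_frames)
  live_chans <- c("H2B", "CRL4", "APCC", "PCNAFOCI")
  last_h2b <- NULL
  for (f in seq(0L, cfg$n_frames - 1L)) {
    rf <- render_live_frame(pop, cfg, f, live_chans)
    corrected <- lapply(rf$images, function(img) {
      raw <- with_seed(cfg$seed * 1000L + f,
                       apply_camera_model(img, cfg, noise = noise))
      pmax((raw - offset_cam) / prof, 0)
    })
    frames_obs[[f + 1L]] <- quantify_live_frame(corrected, f, cfg)
    if (f == cfg$n_frames - 1L) last_h2b <- corrected$H2B
  }
  r_px <- mean(cfg$nucleus_radius_um) / cfg$pixel_size_um
  tracks <- build_tracks(frames_obs, params = list(
    max_dist_px = max(10, 3 * cfg$motion_sigma_px_per_frame),
    vicinity_px = 4 * r_px))

  ann <- annotate_all_tracks(tracks, cfg, site_offset_min)

  # fixed-cell side
  fx <- render_fixed_snapshot(pop, cfg)
  ratio <- cfg$fixed$magnification_ratio %||% 1
  fixed_imgs <- lapply(names(fx$images), function(ch) {
    raw <- with_seed(cfg$seed * 1000L + 5000L + match(ch, names(fx$images)),
                     apply_camera_model_fixed(fx$images[[ch]], cfg, noise = noise))
    raw
  })
  names(fixed_imgs) <- names(fx$images)
  fmask <- segment_fixed(fixed_imgs$DNA,
                         min_area_px = 0.3 * pi * (min(cfg$nucleus_radius_um) /
                                                     cfg$pixel_size_um * ratio)^2)
  fixed_table <- measure_fixed_cells(fixed_imgs, fmask,
                                     cfg$pixel_size_um / ratio)
  off <- register_translation(fixed_imgs$DNA, last_h2b,
                              magnification_ratio = ratio)
  live_last <- tracks$observations[
    tracks$observations$frame == cfg$n_frames - 1L, , drop = FALSE]
  match <- match_fixed_to_live(fixed_table, live_last, off,
                               magnification_ratio = ratio,
                               max_dist_px = r_px)
  movie_end_min <- (cfg$n_frames - 1L) * cfg$frame_interval_min
  records <- assemble_records(fixed_table, tracks, ann, match, live_last,
                              movie_end_min, site_offset_min, site_id, well_id)
  list(records = records, tracks = tracks, annotations = ann,
       population = pop, fixed_truth = fx$truth, offset = off,
       match = match, live_last = live_last, fixed_table = fixed_table)
}

# Fixed snapshots are acquired on a (possibly different) camera; here the
# same offset and noise model are used with a flat profile at the fixed
# scale, and the correction is applied immediately.
apply_camera_model_fixed <- function(image, cfg, noise = TRUE) {
  offset <- cfg$camera$offset %||% 0
  out <- offset + image
  if (noise) {
    v <- (cfg$camera$read_noise_sd %||% 0)^2 +
      (cfg$camera$shot_scale %||% 0) * pmax(image, 0)
    out <- out + matrix(stats::rnorm(length(out), 0, sqrt(v)),
                        nrow(out), ncol(out))
  }
  pmax(out - offset, 0)
}

# Per-cell fixed measurements for all channels under the DNA mask.
measure_fixed_cells <- function(images, mask, pixel_size_um) {
  base <- NULL
  for (ch in names(images)) {
    bg <- estimate_background(images[[ch]], mask, 7.8, pixel_size_um)
    m <- measure_cells(images[[ch]], mask, background = bg,
                       pixel_size_um = pixel_size_um)
    if (is.null(base)) {
      base <- m[, c("label", "x", "y", "area_px")]
    }
    base[[paste0(ch, "_total")]] <- m$total[match(base$label, m$label)]
    base[[paste0(ch, "_mean")]] <- m$mean[match(base$label, m$label)]
  }
  base
}

#' Annotate cell-cycle events on every track
#'
#' Applies [annotate_track()] to each track of a `"cell_tracks"` object,
#' taking anaphase frames from lineage (a daughter's first frame follows the
#' parent's division frame).
#'
#' @param tracks a `"cell_tracks"` object with reporter columns
#'   (`CRL4_total`, `APCC_total`, `puncta_area_px`).
#' @param config the [sim_config()] (frame interval).
#' @param site_offset_min acquisition offset added to event times.
#' @return data frame, one row per track.
#' @export
annotate_all_tracks <- function(tracks, config, site_offset_min = 0) {
  tr <- tracks$tracks; obs <- tracks$observations
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    id <- tr$track_id[i]
    t_obs <- obs[obs$track_id == id, , drop = FALSE]
    t_obs <- t_obs[order(t_obs$frame), , drop = FALSE]
    parent <- tr$parent_track_id[i]
    ana <- if (!is.na(parent))
      tr$division_frame[match(parent, tr$track_id)] else NA_integer_
    a <- annotate_track(
      t_obs,
      channel_map = list(crl4 = "CRL4_total", apcc = "APCC_total",
                         foci = "puncta_area_px"),
      params = list(drop = list(min_expression = 3000)),
      anaphase_frame = ana,
      frame_interval_min = config$frame_interval_min,
      time_offset_min = site_offset_min)
    a$track_id <- id
    a
  })
  do.call(rbind, rows)
}
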