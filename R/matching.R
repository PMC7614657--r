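# RT-QIBC core: register end-point fixed-cell images to the final live
# frame, match fixed cells to live tracks, and emit event-aligned records.

#' Register a fixed image to a live reference by cross-correlation
#'
#' Brings both images to the fixed-image scale (bicubic upsampling of the
#' live image, or mean-value binning of the fixed image), then locates the
#' normalized cross-correlation peak and returns the integer-pixel
#' translation, expressed in fixed-frame pixels: `fixed ~ live (upsampled)
#' shifted by (dx, dy)`.
#'
#' @param fixed_ref fixed-frame reference image (e.g. DNA stain).
#' @param live_ref last live frame of the matching channel (e.g. H2B).
#' @param magnification_ratio fixed-to-live pixel-size ratio (integer >= 1).
#' @param strategy `"upsample_live"` or `"bin_fixed"`.
#' @param min_correlation registration fails below this peak normalized
#'   correlation.
#' @return named numeric `c(dx, dy)` in fixed-frame pixels.
#' @export
register_translation <- function(fixed_ref, live_ref, magnification_ratio = 1,
                                 strategy = c("upsample_live", "bin_fixed"),
                                 min_correlation = 0.1) {
  strategy <- match.arg(strategy)
  k <- as.integer(round(magnification_ratio))
  if (k < 1) stopf("magnification ratio must be >= 1")
  scale_out <- 1
  if (k > 1) {
    if (strategy == "upsample_live") {
      live_ref <- bicubic_upsample(live_ref, k)
    } else {
      fixed_ref <- bin_mean(fixed_ref, k)
      scale_out <- k
    }
  }
  nr <- min(nrow(fixed_ref), nrow(live_ref))
  nc <- min(ncol(fixed_ref), ncol(live_ref))
  a <- fixed_ref[seq_len(nr), seq_len(nc)]; b <- live_ref[seq_len(nr), seq_len(nc)]
  a <- a - mean(a); b <- b - mean(b)
  # circular cross-correlation via FFT
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  peak <- which.max(cc)
  # R's inverse fft is unscaled: cc / N is the circular cross-correlation sum
  corr <- (cc[peak] / length(a)) / sqrt(sum(a^2) * sum(b^2))
  if (!is.finite(corr) || corr < min_correlation)
    stopf("registration failed: peak correlation %.3f below %.3f",
          corr, min_correlation)
  dy <- ((peak - 1L) %% nr)
  dx <- ((peak - 1L) %/% nr)
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dx = dx * scale_out, dy = dy * scale_out)
}

#' Match fixed cells to their nearest live-cell neighbours
#'
#' Fixed-frame centroids are mapped into live coordinates
#' (`(c - offset) / ratio`) and greedily assigned, in ascending distance
#' order, to the nearest live cell within `max_dist_px` (live-frame px);
#' each live cell receives at most one fixed cell. Unmatched fixed cells are
#' dropped (their count is returned as an attribute).
#'
#' @param fixed_centroids data frame with `x`, `y` (fixed-frame px).
#' @param live_centroids data frame with `x`, `y` (live-frame px).
#' @param offset `c(dx, dy)` from [register_translation()] (fixed-frame px).
#' @param magnification_ratio fixed-to-live pixel ratio.
#' @param max_dist_px maximum match distance in live-frame px.
#' @return data frame `fixed` (row in `fixed_centroids`), `live` (row in
#'   `live_centroids`), `dist_px`; attribute `n_dropped`.
#' @export
match_fixed_to_live <- function(fixed_centroids, live_centroids, offset,
                                magnification_ratio = 1, max_dist_px = 10) {
  nf <- nrow(fixed_centroids); nl <- nrow(live_centroids)
  out <- data.frame(fixed = integer(), live = integer(), dist_px = numeric())
  if (nf == 0 || nl == 0) {
    attr(out, "n_dropped") <- nf
    return(out)
  }
  fx <- (fixed_centroids$x - offset[["dx"]]) / magnification_ratio
  fy <- (fixed_centroids$y - offset[["dy"]]) / magnification_ratio
  d <- sqrt(outer(fx, live_centroids$x, `-`)^2 +
              outer(fy, live_centroids$y, `-`)^2)
  cand <- which(d <= max_dist_px, arr.ind = TRUE)
  if (nrow(cand)) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_f <- logical(nf); used_l <- logical(nl)
    rows <- list()
    for (i in seq_len(nrow(cand))) {
      f <- cand[i, 1]; l <- cand[i, 2]
      if (used_f[f] || used_l[l]) next
      used_f[f] <- TRUE; used_l[l] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(fixed = f, live = l,
                                              dist_px = d[f, l])
    }
    if (length(rows)) out <- do.call(rbind, rows)
  }
  attr(out, "n_dropped") <- nf - nrow(out)
  out
}

#' Acquisition-time offset of an imaging site
#'
#' Sites are imaged in a fixed order within each frame interval; a site's
#' acquisition offset is its 0-based ordinal position in the cycle divided by
#' the number of positions, times the frame interval.
#'
#' @param site_id site identifier.
#' @param schedule data frame with columns `site_id` and `position`
#'   (0-based acquisition order), or a vector of site ids in acquisition
#'   order.
#' @param frame_interval_min minutes per frame.
#' @return offset in minutes.
#' @export
assign_acquisition_times <- function(site_id, schedule, frame_interval_min) {
  if (is.data.frame(schedule)) {
    pos <- schedule$position[match(site_id, schedule$site_id)]
    n <- nrow(schedule)
  } else {
    pos <- match(site_id, schedule) - 1L
    n <- length(schedule)
  }
  if (any(is.na(pos))) stopf("unknown site id")
  pos / n * frame_interval_min
}

#' Align multi-round staining images to a common round
#'
#' Registers each round's DNA image to the first round; the first round's
#' segmentation mask is designated the primary mask and all rounds are
#' quantified under it, shifted by the per-round offset. Rounds that fail to
#' register get `NA` offsets (their channels are reported as missing).
#'
#' @param round_images list of per-round DNA images.
#' @return data frame `round`, `dx`, `dy` (`NA` on registration failure).
#' @export
align_staining_rounds <- function(round_images) {
  if (length(round_images) < 2) stopf("need >= 2 rounds")
  ref <- round_images[[1]]
  out <- data.frame(round = seq_along(round_images), dx = 0, dy = 0)
  for (i in seq_along(round_images)[-1]) {
    off <- tryCatch(register_translation(round_images[[i]], ref),
                    error = function(e) c(dx = NA_real_, dy = NA_real_))
    out$dx[i] <- off[["dx"]]; out$dy[i] <- off[["dy"]]
  }
  out
}

#' Assemble event-aligned RT-QIBC records
#'
#' Joins matched fixed-cell measurements to live tracks and their event
#' annotations, and derives time-since-event fields:
#' `time = (movie_end_time + site_offset) - event_time`. Records whose event
#' is unannotated keep their measurements with `NA` times. Output is sorted
#' by (well, site, track).
#'
#' @param fixed_table data frame of per-fixed-cell measurements (must carry
#'   a row per cell, in the order referenced by `assignment$fixed`).
#' @param tracks a `"cell_tracks"` object.
#' @param annotations data frame from [annotate_track()] rows (per track,
#'   times in minutes including any site offset).
#' @param assignment data frame from [match_fixed_to_live()] with an added
#'   `track_id` column, or with `live` indexing `live_table` rows that carry
#'   `track_id`.
#' @param live_table data frame of live last-frame cells (with `track_id`)
#'   that `assignment$live` indexes.
#' @param movie_end_min time of the last live frame (minutes).
#' @param site_offset_min acquisition offset of this site (minutes).
#' @param site_id,well_id identifiers attached to the records.
#' @return data frame of RT-QIBC records.
#' @export
assemble_records <- function(fixed_table, tracks, annotations, assignment,
                             live_table, movie_end_min,
                             site_offset_min = 0, site_id = 1L, well_id = 1L) {
  if (nrow(assignment) == 0) return(data.frame())
  if (any(assignment$fixed > nrow(fixed_table)) ||
      any(assignment$live > nrow(live_table)))
    stopf("assignment references unknown ids")
  track_ids <- live_table$track_id[assignment$live]
  if (any(!track_ids %in% tracks$tracks$track_id))
    stopf("assignment references unknown track ids")
  rec <- fixed_table[assignment$fixed, , drop = FALSE]
  names(rec) <- paste0("fixed_", names(rec))
  rec$track_id <- track_ids
  rec$match_distance_px <- assignment$dist_px
  rec$site_id <- site_id
  rec$well_id <- well_id
  ann <- annotations[match(track_ids, annotations$track_id), , drop = FALSE]
  fix_time <- movie_end_min + site_offset_min
  rec$fixation_time_min <- fix_time
  rec$time_since_anaphase_min <- fix_time - ann$anaphase_min
  rec$time_since_apcc_inactivation_min <- fix_time - ann$apcc_inactivation_min
  rec$time_since_s_entry_min <- fix_time - ann$s_entry_min
  rec$s_entry_frame <- ann$s_entry_frame
  rec$s_entry_source <- ann$s_entry_source
  rec <- rec[order(rec$well_id, rec$site_id, rec$track_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
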