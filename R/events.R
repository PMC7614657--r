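# Cell-cycle event detection on per-track reporter traces: degradation onset
# (CRL4-Cdt2 activation), accumulation onset (APC/C-Cdh1 inactivation), and
# PCNA-foci S-phase entry.
#
# Frame indices are 0-based throughout, matching the observation tables.

ls_slope <- function(y) {
  x <- seq_along(y) - 1
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Detect a degradation (drop) onset in a reporter trace
#'
#' Scans the trace (normalized per cell to its running maximum from
#' `search_start`) for the earliest frame `t` where, over the fixed
#' look-ahead window `[t, t + window_frames]`, the fitted slope is
#' sufficiently negative, the local curvature at `t` marks a peak/corner, and
#' the normalized decrease over the window reaches `min_drop_frac`. Using a
#' fixed look-ahead window makes detection latency independent of how long
#' before fixation the drop occurred.
#'
#' @param trace numeric vector (one value per frame; integrated nuclear
#'   reporter intensity).
#' @param search_start first 0-based frame eligible as onset (>= 1).
#' @param window_frames look-ahead window length (frames).
#' @param slope_max maximum (i.e. most positive allowed) fitted slope over
#'   the window, per frame, on the normalized trace.
#' @param curvature_min minimum peak curvature at `t`
#'   (`2 x[t] - x[t-1] - x[t+1]` on the normalized trace).
#' @param min_drop_frac minimum normalized decrease across the window.
#' @param pre_level_frac the frame before the onset must be at least this
#'   fraction of the onset level (degradation starts from a plateau or a
#'   rising peak; one-frame spikes do not qualify).
#' @param min_expression minimum overall trace maximum (absolute units)
#'   required before any onset is called; traces of cells that never express
#'   the reporter above this level are not annotatable.
#' @return 0-based onset frame, or `NA` if no frame qualifies.
#' @export
detect_drop_onset <- function(trace, search_start = 1L, window_frames = 3L,
                              slope_max = -0.03, curvature_min = 0.01,
                              min_drop_frac = 0.10, pre_level_frac = 0.75,
                              min_expression = 0) {
  n <- length(trace)
  search_start <- max(1L, as.integer(search_start))
  if (n < search_start + window_frames + 1L) return(NA_integer_)
  # slope and curvature on the trace normalized to its running maximum from
  # search_start; the drop criterion is taken against the cell's overall
  # expression (global maximum), so near-zero noisy traces cannot qualify
  idx <- (search_start + 1L):n         # 1-based positions
  x <- trace
  x[idx] <- trace[idx] / pmax(cummax(trace[idx]), 1e-12)
  x[seq_len(search_start)] <- trace[seq_len(search_start)] /
    max(trace[idx][1], 1e-12)
  expr_max <- max(trace[idx], 1e-12)
  if (expr_max < min_expression) return(NA_integer_)
  for (t in search_start:(n - window_frames - 1L)) {
    i <- t + 1L                        # 1-based position of frame t
    win <- x[i:(i + window_frames)]
    if (ls_slope(win) > slope_max) next
    kappa <- 2 * x[i] - x[i - 1L] - x[i + 1L]
    if (kappa < curvature_min) next
    if ((trace[i] - trace[i + window_frames]) / expr_max < min_drop_frac) next
    if (trace[i - 1L] < pre_level_frac * trace[i]) next
    return(t)
  }
  NA_integer_
}

#' Detect an accumulation (rise) onset in a reporter trace
#'
#' Returns the earliest frame where the fitted forward slope of the
#' max-normalized trace reaches `slope_min`, the level at that frame is still
#' low (`<= low_level_max`), and the trace subsequently climbs to
#' `persist_level` without returning below the low level (persistence
#' clause, rejecting transient blips).
#'
#' @param trace numeric vector (one value per frame).
#' @param search_start first 0-based frame eligible as onset.
#' @param window_frames forward window for the slope fit (frames).
#' @param slope_min minimum fitted forward slope (per frame, normalized).
#' @param low_level_max maximum normalized level at onset.
#' @param persist_level normalized level the trace must reach afterwards.
#' @return 0-based onset frame, or `NA`.
#' @export
detect_rise_onset <- function(trace, search_start = 0L, window_frames = 3L,
                              slope_min = 0.02, low_level_max = 0.1,
                              persist_level = 0.25) {
  n <- length(trace)
  search_start <- max(0L, as.integer(search_start))
  if (n < search_start + window_frames + 2L) return(NA_integer_)
  mx <- max(trace[(search_start + 1L):n])
  if (mx <= 0) return(NA_integer_)
  x <- trace / mx
  for (t in search_start:(n - window_frames - 1L)) {
    i <- t + 1L
    win <- x[i:(i + window_frames)]
    if (ls_slope(win) < slope_min) next
    if (x[i] > low_level_max) next
    if (x[i + 1L] <= x[i]) next      # the rise must begin immediately
    later <- x[(i + 1L):n]
    reach <- which(later >= persist_level)[1]
    if (is.na(reach)) next
    # once above the low level, the trace must not dip back below it
    # before reaching the persistence level
    above <- which(later > low_level_max)[1]
    if (!is.na(above) && above < reach &&
        any(later[above:reach] < low_level_max)) next
    return(t)
  }
  NA_integer_
}

#' Detect S-phase entry from a PCNA foci-area trace (dual threshold)
#'
#' Finds the first frame `h` whose foci area exceeds `high_thresh_px` and is
#' greater than each of the previous `lookback_frames` values; S entry is the
#' final frame before `h` whose foci area is below `low_thresh_px`.
#'
#' @param foci_area per-frame foci area (px).
#' @param high_thresh_px high threshold robustly identifying S-phase cells.
#' @param low_thresh_px low threshold marking pre-S baseline.
#' @param lookback_frames number of previous frames `h` must exceed.
#' @return 0-based S-entry frame, or `NA`.
#' @export
detect_s_entry_foci <- function(foci_area, high_thresh_px = 50,
                                low_thresh_px = 3, lookback_frames = 4L) {
  if (low_thresh_px >= high_thresh_px) stopf("low threshold must be < high")
  n <- length(foci_area)
  for (i in seq_len(n)) {
    if (foci_area[i] <= high_thresh_px) next
    lb <- max(1L, i - lookback_frames):(i - 1L)
    if (i > 1 && any(foci_area[lb] >= foci_area[i])) next
    before <- which(foci_area[seq_len(i - 1L)] < low_thresh_px)
    if (length(before) == 0) return(NA_integer_)
    return(before[length(before)] - 1L)   # 0-based
  }
  NA_integer_
}

#' Annotate cell-cycle events on one track
#'
#' Applies the appropriate detector per configured channel: the drop detector
#' to the integrated CRL4-Cdt2 reporter intensity, the rise detector to the
#' integrated APC/C-Cdh1 reporter intensity, and the dual-threshold (or, for
#' wide-field foci-area traces, the rise) detector to the PCNA foci-area
#' trace. The anaphase frame comes from lineage (the track's first frame when
#' it has a parent). S entry falls back to the CRL4 drop when no foci channel
#' is present.
#'
#' @param track data frame of one track's observations, ordered by `frame`,
#'   with reporter columns.
#' @param channel_map named list mapping roles to column names, e.g.
#'   `list(crl4 = "CRL4_total", apcc = "APCC_total", foci = "puncta_area_px")`;
#'   omit roles the track lacks.
#' @param params list of detector parameter overrides (`drop`, `rise`,
#'   `foci` sublists); `foci$method` may be `"dual_threshold"` (default) or
#'   `"rise"`.
#' @param anaphase_frame 0-based anaphase frame from lineage, or `NA`.
#' @param frame_interval_min minutes per frame (for the `*_min` fields).
#' @param time_offset_min acquisition-time offset for this site/well.
#' @return one-row data frame: `anaphase_frame`, `crl4_activation_frame`,
#'   `apcc_inactivation_frame`, `s_entry_frame`, `s_entry_source`, plus the
#'   same events in minutes.
#' @export
annotate_track <- function(track, channel_map, params = list(),
                           anaphase_frame = NA_integer_,
                           frame_interval_min = 1,
                           time_offset_min = 0) {
  frames0 <- track$frame
  rel_search <- if (!is.na(anaphase_frame))
    max(1L, which(frames0 == anaphase_frame)) else 1L

  get_trace <- function(role) {
    cn <- channel_map[[role]]
    if (is.null(cn) || !cn %in% names(track)) return(NULL)
    track[[cn]]
  }
  to_abs <- function(rel) if (is.na(rel)) NA_integer_ else frames0[rel + 1L]

  crl4 <- get_trace("crl4")
  crl4_f <- if (!is.null(crl4))
    to_abs(do.call(detect_drop_onset,
                   c(list(trace = crl4, search_start = rel_search),
                     params$drop %||% list())))
  else NA_integer_

  apcc <- get_trace("apcc")
  apcc_f <- if (!is.null(apcc))
    to_abs(do.call(detect_rise_onset,
                   c(list(trace = apcc, search_start = rel_search - 1L),
                     params$rise %||% list())))
  else NA_integer_

  foci <- get_trace("foci")
  s_source <- NA_character_
  s_f <- NA_integer_
  if (!is.null(foci)) {
    fp <- params$foci %||% list()
    method <- fp$method %||% "dual_threshold"
    fp$method <- NULL
    s_rel <- if (identical(method, "rise"))
      do.call(detect_rise_onset, c(list(trace = foci), fp))
    else do.call(detect_s_entry_foci, c(list(foci_area = foci), fp))
    s_f <- to_abs(s_rel)
    if (!is.na(s_f)) s_source <- "pcna_foci"
  }
  if (is.na(s_f) && !is.na(crl4_f)) {
    s_f <- crl4_f
    s_source <- "crl4_reporter"
  }
  mins <- function(f) if (is.na(f)) NA_real_ else
    f * frame_interval_min + time_offset_min
  data.frame(
    track_id = track$track_id[1] %||% NA_integer_,
    anaphase_frame = anaphase_frame,
    crl4_activation_frame = crl4_f,
    apcc_inactivation_frame = apcc_f,
    s_entry_frame = s_f,
    s_entry_source = s_source,
    anaphase_min = mins(anaphase_frame),
    crl4_activation_min = mins(crl4_f),
    apcc_inactivation_min = mins(apcc_f),
    s_entry_min = mins(s_f)
  )
}
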