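# Per-cell signal extraction: background estimation, nuclear and
# cytoplasmic-ring statistics, puncta area, staining-round corrections.

#' Estimate the image background outside dilated nuclei
#'
#' Returns the 25th percentile of pixels outside the nuclear mask dilated by
#' `dilation_um` (7.8 um for predominantly nuclear signals, 15.6 um for
#' signals with cytoplasmic components).
#'
#' @param image flat-field-corrected image.
#' @param mask integer label matrix of nuclei.
#' @param dilation_um dilation radius in microns.
#' @param pixel_size_um microns per pixel.
#' @return background level (a.u.).
#' @export
estimate_background <- function(image, mask, dilation_um = 7.8,
                                pixel_size_um = 0.65) {
  r_px <- round(dilation_um / pixel_size_um)
  outside <- !dilate_mask(mask > 0, r_px)
  if (!any(outside)) stopf("no background pixels left after dilation")
  as.numeric(stats::quantile(image[outside], 0.25))
}

#' Measure per-cell nuclear (and ring) signal statistics
#'
#' For each labelled nucleus: mean, median and total background-subtracted
#' intensity over the object's pixels. If `ring_um` is given, the median over
#' an annulus between dilations by the inner and outer radii is added,
#' excluding pixels belonging to any nucleus or any other nucleus's inner
#' dilation; `cdk_activity = ring_median / nuclear_median` when both are
#' defined.
#'
#' @param image flat-field-corrected image.
#' @param mask integer label matrix.
#' @param background scalar background level to subtract (>= 0).
#' @param ring_um length-2 `c(inner, outer)` annulus bounds in um, or `NULL`.
#' @param pixel_size_um microns per pixel.
#' @return data frame with one row per cell: `label`, `x`, `y` (0-based
#'   centroids), `area_px`, `total`, `mean`, `median`, and when requested
#'   `ring_median`, `cdk_activity` (`NA` when the ring is fully occluded).
#' @export
measure_cells <- function(image, mask, background = 0, ring_um = NULL,
                          pixel_size_um = 0.65) {
  if (background < 0) stopf("background must be >= 0")
  cen <- label_centroids(mask)
  if (nrow(cen) == 0) return(cbind(cen, total = numeric(), mean = numeric(),
                                   median = numeric()))
  img <- image - background
  idx <- which(mask > 0)
  lab <- factor(mask[idx], levels = cen$label)
  vals <- img[idx]
  out <- data.frame(
    label = cen$label, x = cen$x, y = cen$y, area_px = cen$area,
    total = as.numeric(tapply(vals, lab, sum)),
    mean = as.numeric(tapply(vals, lab, mean)),
    median = as.numeric(tapply(vals, lab, stats::median))
  )
  if (!is.null(ring_um)) {
    if (!(ring_um[1] > 0 && ring_um[2] > ring_um[1]))
      stopf("ring bounds must satisfy 0 < inner < outer")
    r_in <- max(1L, round(ring_um[1] / pixel_size_um))
    r_out <- round(ring_um[2] / pixel_size_um)
    out$ring_median <- NA_real_
    for (i in seq_len(nrow(out))) {
      obj <- mask == out$label[i]
      # annulus between the inner and outer dilations, excluding pixels of
      # any other nucleus or its inner dilation
      other <- mask > 0 & !obj
      ring <- dilate_mask(obj, r_out) & !dilate_mask(obj, r_in) &
        !dilate_mask(other, r_in)
      if (any(ring)) out$ring_median[i] <- stats::median(img[ring])
    }
    out$cdk_activity <- ifelse(is.na(out$ring_median) | out$median == 0,
                               NA_real_, out$ring_median / out$median)
  }
  out
}

#' Measure per-cell puncta area with a top-hat filter
#'
#' Applies a morphological top-hat of the given radius and counts, per
#' nucleus, pixels above the selected threshold. Thresholds are an ordered
#' series of increasing stringency; `threshold_index` selects one.
#'
#' @param image flat-field-corrected image.
#' @param mask integer label matrix.
#' @param tophat_radius_px top-hat structuring-element radius (3 for
#'   confocal, 2 for wide-field imaging).
#' @param thresholds strictly increasing threshold series (a.u.).
#' @param threshold_index which threshold to apply.
#' @return data frame `label`, `puncta_area_px`.
#' @export
measure_puncta_area <- function(image, mask, tophat_radius_px = 2,
                                thresholds, threshold_index = 1L) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stopf("thresholds must be strictly increasing")
  th <- tophat_gray(image, tophat_radius_px)
  cen <- label_centroids(mask)
  hot <- th > thresholds[threshold_index]
  idx <- which(mask > 0)
  lab <- factor(mask[idx], levels = cen$label)
  data.frame(label = cen$label,
             puncta_area_px = as.integer(tapply(hot[idx], lab, sum)))
}

#' Remove incompletely extracted cells
#'
#' Cells whose residual soluble-reporter signal exceeds the gate are
#' considered incompletely pre-extracted and removed.
#'
#' @param records data frame of per-cell records.
#' @param soluble_signal per-cell residual soluble signal (a.u.).
#' @param gate threshold (from [derive_gate()] on control cells).
#' @return filtered records, with attribute `n_removed`.
#' @export
filter_extraction_artifacts <- function(records, soluble_signal, gate) {
  keep <- !(soluble_signal > gate)
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Correct residual signal carried over between staining rounds
#'
#' `round2 - scale * round1`, floored at zero, with an empirically determined
#' residual scaling factor.
#'
#' @param round2,round1 per-cell signals from the two rounds (a.u.).
#' @param scale residual scaling factor (>= 0).
#' @return corrected per-cell signal.
#' @export
correct_round_residual <- function(round2, round1, scale) {
  if (scale < 0) stopf("scale must be >= 0")
  if (length(round2) != length(round1)) stopf("length mismatch")
  pmax(round2 - scale * round1, 0)
}

#' Normalize a signal by a co-expressed marker
#'
#' Element-wise ratio to a co-expressed marker (e.g. a bicistronic H2B
#' fusion), controlling for per-cell expression of the construct.
#'
#' @param values per-cell signal.
#' @param marker_values per-cell marker signal (> 0; zero yields `NA`).
#' @return per-cell ratios.
#' @export
normalize_by_coexpressed_marker <- function(values, marker_values) {
  if (length(values) != length(marker_values)) stopf("length mismatch")
  ifelse(marker_values > 0, values / marker_values, NA_real_)
}
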