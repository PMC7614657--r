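# Flat-field (shading) and spectral bleedthrough correction.

#' Estimate the illumination profile from background pixels
#'
#' Aggregates background autofluorescence across many imaging sites: pixels
#' under any foreground mask are excluded, the per-pixel median across images
#' is taken, gaps are filled by smooth interpolation, the field is low-pass
#' filtered at field scale and normalized to mean 1. The camera offset is
#' taken from `camera_offset` when given, otherwise estimated as a low
#' percentile of the aggregated field.
#'
#' @param images list of raw images (matrices, detector counts).
#' @param foreground_masks list of label maps (or `NULL` for blank-well
#'   images, method `"blank_well"`).
#' @param method `"background_aggregate"` (mask out cells) or `"blank_well"`.
#' @param camera_offset known camera offset in counts, or `NULL` to estimate.
#' @param mask_dilation_px dilation applied to foreground masks before
#'   exclusion, so nuclear flanks do not leak into the background estimate.
#' @param smooth_frac Gaussian sigma for profile smoothing, as a fraction of
#'   image width.
#' @return list of class `"illumination_profile"`: `profile` (mean-1 gain
#'   field), `camera_offset`, `source`.
#' @export
estimate_illumination <- function(images, foreground_masks = NULL,
                                  method = c("background_aggregate", "blank_well"),
                                  camera_offset = NULL,
                                  mask_dilation_px = 4,
                                  smooth_frac = 0.05) {
  method <- match.arg(method)
  if (method == "background_aggregate") {
    if (length(images) < 10)
      stopf("background_aggregate requires >= 10 images")
    if (is.null(foreground_masks))
      stopf("background_aggregate requires foreground masks")
  }
  dims <- dim(images[[1]])
  acc <- array(NA_real_, c(dims[1], dims[2], length(images)))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!is.null(foreground_masks) && !is.null(foreground_masks[[i]])) {
      fg <- dilate_mask(foreground_masks[[i]] > 0, mask_dilation_px)
      img[fg] <- NA_real_
    }
    acc[, , i] <- img
  }
  n_obs <- apply(!is.na(acc), c(1, 2), sum)
  if (mean(n_obs >= 3) < 0.5)
    stopf("insufficient background coverage: <50%% of pixels have >= 3 observations")
  med <- apply(acc, c(1, 2), stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    fill <- stats::median(med, na.rm = TRUE)
    med[is.na(med)] <- fill
  }
  offset <- camera_offset %||% as.numeric(stats::quantile(med, 0.001))
  field <- med - offset
  if (all(field <= 0))
    stopf("no background signal above the camera offset: profile undefined")
  sm <- gauss_smooth_mirror(field, sigma = smooth_frac * ncol(field))
  if (any(sm <= 0))
    stopf("estimated profile not strictly positive")
  structure(list(profile = sm / mean(sm), camera_offset = offset,
                 source = method),
            class = "illumination_profile")
}

#' Flat-field correct an image
#'
#' Subtracts the camera offset and divides by the illumination profile,
#' clipping at zero: `(image - offset) / profile`.
#'
#' @param image raw image (matrix, detector counts).
#' @param profile an `"illumination_profile"` (or plain matrix, offset 0).
#' @return corrected image (matrix).
#' @export
flatfield_correct <- function(image, profile) {
  if (inherits(profile, "illumination_profile")) {
    prof <- profile$profile
    offset <- profile$camera_offset
  } else {
    prof <- profile
    offset <- 0
  }
  if (!all(dim(prof) == dim(image)))
    stopf("profile shape %s does not match image %s",
          paste(dim(prof), collapse = "x"), paste(dim(image), collapse = "x"))
  pmax((image - offset) / prof, 0)
}

#' Correct spectral bleedthrough
#'
#' Subtracts a linear contamination of the target channel by a co-acquired
#' source channel: `target - coefficient * source`, clipped at zero. Both
#' images must already be flat-field corrected.
#'
#' @param target,source corrected images (matrices, same shape).
#' @param coefficient bleedthrough coefficient in `[0, 1)`.
#' @return corrected target image.
#' @export
correct_bleedthrough <- function(target, source, coefficient) {
  if (coefficient < 0 || coefficient >= 1)
    stopf("coefficient must lie in [0, 1)")
  if (!all(dim(target) == dim(source))) stopf("shape mismatch")
  pmax(target - coefficient * source, 0)
}
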