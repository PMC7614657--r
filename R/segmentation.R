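# Nuclear segmentation: multiscale Laplacian-of-Gaussian blob detection for
# live H2B images, histogram-curvature thresholding for fixed DNA stains, and
# curvature-based splitting of touching nuclei.

# Separable convolution (replicate boundary): ky along rows (y), kx along
# columns (x); compiled.
sep_conv <- function(img, ky, kx) sep_conv_cpp(img, ky, kx)

# Scale-normalized negative LoG response (positive at bright blobs),
# computed separably: -sigma^2 * (Gyy*I + Gxx*I).
log_response <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  ax <- seq(-r, r)
  g <- exp(-ax^2 / (2 * sigma^2)); g <- g / sum(g)
  g2 <- g * (ax^2 - sigma^2) / sigma^4
  g2 <- g2 - mean(g2)          # flat-field response exactly zero
  -sigma^2 * (sep_conv(img, g2, g) + sep_conv(img, g, g2))
}

gauss_sep <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  g <- stats::dnorm(seq(-r, r), sd = sigma); g <- g / sum(g)
  sep_conv(img, g, g)
}

#' Detect nuclei with a multiscale Laplacian-of-Gaussian blob detector
#'
#' Scale-normalized LoG responses are computed over a small set of scales
#' spanning the expected nuclear diameter range; local maxima above
#' `detection_threshold` seed objects, duplicate detections of the same
#' nucleus are suppressed by keeping the stronger response, and each seed's
#' extent is obtained by local thresholding at a fraction of the seed's peak
#' amplitude above the local background. Optionally a region-based
#' active-contour refinement (fixed iteration budget) adjusts boundaries.
#'
#' @param image flat-field-corrected image (matrix).
#' @param diameter_range_um expected nuclear diameter range (um).
#' @param pixel_size_um microns per pixel.
#' @param detection_threshold minimum scale-normalized LoG response (counts).
#' @param refine logical; run active-contour refinement (for low-contrast
#'   movies).
#' @param n_scales number of log-spaced scales.
#' @param extent_frac local-threshold fraction of (peak - background).
#' @param min_area_px minimum object area; default 30% of the area implied by
#'   the smallest diameter.
#' @return integer label matrix (0 = background).
#' @export
detect_nuclei_log <- function(image, diameter_range_um, pixel_size_um,
                              detection_threshold = 20, refine = FALSE,
                              n_scales = 3, extent_frac = 0.08,
                              min_area_px = NULL) {
  if (any(diameter_range_um <= 0)) stopf("diameter range must be positive")
  if (all(image == image[1])) return(matrix(0L, nrow(image), ncol(image)))
  d_px <- sort(diameter_range_um / pixel_size_um)
  # rendering truncates blobs at 2.5 sigma, so radius ~ 2.5 sigma
  sigmas <- exp(seq(log(d_px[1] / 5), log(d_px[2] / 5), length.out = n_scales))
  if (is.null(min_area_px)) min_area_px <- 0.3 * pi * (d_px[1] / 2)^2

  resp_best <- matrix(-Inf, nrow(image), ncol(image))
  sigma_best <- matrix(sigmas[1], nrow(image), ncol(image))
  smooth_small <- NULL
  for (s in sigmas) {
    r <- log_response(image, s)
    upd <- r > resp_best
    resp_best[upd] <- r[upd]
    sigma_best[upd] <- s
    if (is.null(smooth_small))
      smooth_small <- gauss_sep(image, sigmas[1] / 2)
  }
  # local maxima of the best response
  mx <- EBImage::dilate(resp_best, EBImage::makeBrush(3, "box"))
  is_max <- resp_best >= mx & resp_best > detection_threshold
  idx <- which(is_max)
  if (length(idx) == 0) return(matrix(0L, nrow(image), ncol(image)))
  seeds <- data.frame(
    row = ((idx - 1L) %% nrow(image)) + 1L,
    col = ((idx - 1L) %/% nrow(image)) + 1L,
    resp = resp_best[idx], sigma = sigma_best[idx]
  )
  seeds <- seeds[order(-seeds$resp), ]
  # suppress duplicate detections of the same nucleus (the stronger response
  # wins); the margin is kept small so nearly-coincident nuclei still
  # produce two seeds
  keep <- rep(TRUE, nrow(seeds))
  min_sep <- 0.35 * d_px[1]
  for (i in seq_len(nrow(seeds))) {
    if (!keep[i]) next
    if (i < nrow(seeds)) {
      j <- (i + 1):nrow(seeds)
      d <- sqrt((seeds$row[j] - seeds$row[i])^2 + (seeds$col[j] - seeds$col[i])^2)
      keep[j][d < min_sep] <- FALSE
    }
  }
  seeds <- seeds[keep, , drop = FALSE]

  # each seed claims thresholded pixels near it; contested pixels go to the
  # nearest seed, so assignments at touching nuclei are stable across frames
  labels <- matrix(0L, nrow(image), ncol(image))
  bestd <- matrix(Inf, nrow(image), ncol(image))
  kept <- 0L
  for (i in seq_len(nrow(seeds))) {
    r_est <- 2.5 * seeds$sigma[i]
    w <- ceiling(1.6 * r_est)
    rows <- max(1L, seeds$row[i] - w):min(nrow(image), seeds$row[i] + w)
    cols <- max(1L, seeds$col[i] - w):min(ncol(image), seeds$col[i] + w)
    win <- image[rows, cols, drop = FALSE]
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    bg <- stats::median(border)
    peak <- smooth_small[seeds$row[i], seeds$col[i]]
    if (peak <= bg) next
    thr <- bg + extent_frac * (peak - bg)
    d2 <- outer((rows - seeds$row[i])^2, (cols - seeds$col[i])^2, `+`)
    sel <- win > thr & d2 <= (1.3 * r_est)^2
    if (sum(sel) < min_area_px) next
    kept <- kept + 1L
    sub_l <- labels[rows, cols]; sub_d <- bestd[rows, cols]
    upd <- sel & d2 < sub_d
    sub_l[upd] <- kept; sub_d[upd] <- d2[upd]
    labels[rows, cols] <- sub_l; bestd[rows, cols] <- sub_d
  }
  labels <- relabel_sequential(labels)
  if (refine) labels <- refine_active_contour(image, labels)
  labels
}

relabel_sequential <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- labels
  out[labels > 0] <- map[labels[labels > 0]]
  out
}

# Region-based (piecewise-constant) active-contour refinement: per object,
# iterate assignment to inside/outside means within a window, with a
# smoothing (majority) step; fixed iteration budget.
refine_active_contour <- function(image, labels, iterations = 50) {
  out <- matrix(0L, nrow(image), ncol(image))
  ids <- sort(unique(labels[labels > 0]))
  maj <- EBImage::makeBrush(3, "box")
  for (id in ids) {
    obj <- labels == id
    idx <- which(obj, arr.ind = TRUE)
    w <- 6L
    rows <- max(1L, min(idx[, 1]) - w):min(nrow(image), max(idx[, 1]) + w)
    cols <- max(1L, min(idx[, 2]) - w):min(ncol(image), max(idx[, 2]) + w)
    win <- image[rows, cols, drop = FALSE]
    m <- obj[rows, cols, drop = FALSE]
    other <- labels[rows, cols, drop = FALSE] > 0 & !m
    for (it in seq_len(iterations)) {
      c1 <- mean(win[m]); c2 <- mean(win[!m & !other])
      if (!is.finite(c2)) break
      new_m <- (win - c1)^2 < (win - c2)^2 & !other
      # regularize: keep pixels with majority support in 3x3 neighbourhood
      sm <- EBImage::filter2(new_m * 1, maj / sum(maj))
      new_m <- sm > 0.5 & !other
      if (identical(new_m, m)) break
      m <- new_m
    }
    # keep the component containing the original centroid
    lab_w <- EBImage::bwlabel(m * 1)
    cen <- round(colMeans(idx))
    comp <- lab_w[cen[1] - rows[1] + 1L, cen[2] - cols[1] + 1L]
    if (comp == 0) {
      tab <- tabulate(lab_w[lab_w > 0])
      comp <- which.max(tab)
    }
    sel <- lab_w == comp
    sub <- out[rows, cols]
    sub[sel & sub == 0L] <- id
    out[rows, cols] <- sub
  }
  relabel_sequential(out)
}

#' Global threshold from histogram curvature
#'
#' Builds a histogram of log intensities, smooths it, and returns the
#' intensity at maximum curvature of the descending background shoulder
#' (the foot of the background peak). Binning in the log domain makes the
#' returned threshold scale-covariant: doubling all intensities doubles it.
#'
#' @param image image with both background and foreground pixels.
#' @param n_bins number of histogram bins.
#' @param smooth_sigma_bins Gaussian smoothing of the counts (bins).
#' @return threshold intensity (strictly between the histogram mode and
#'   maximum).
#' @export
threshold_histogram_curvature <- function(image, n_bins = 256,
                                          smooth_sigma_bins = 3) {
  v <- log(image[image > 0])
  if (length(v) < 100 || diff(range(v)) < 1e-8)
    stopf("degenerate histogram: image lacks distinct background and foreground")
  br <- seq(min(v), max(v), length.out = n_bins + 1)
  cnt <- tabulate(findInterval(v, br, all.inside = TRUE), nbins = n_bins)
  # mirror-padded Gaussian smoothing of the counts
  ksz <- ceiling(3 * smooth_sigma_bins)
  kern <- stats::dnorm(seq(-ksz, ksz), sd = smooth_sigma_bins)
  kern <- kern / sum(kern)
  padded <- c(rev(cnt[seq_len(ksz)]), cnt, rev(cnt[(n_bins - ksz + 1):n_bins]))
  sm <- stats::filter(padded, kern, sides = 2)[(ksz + 1):(ksz + n_bins)]
  mode_bin <- which.max(sm)
  if (mode_bin >= n_bins - 2)
    stopf("degenerate histogram: no descending shoulder above the mode")
  # on log-counts a Gaussian background shoulder is a parabola (constant
  # curvature); the curvature maximum marks its foot, where the shoulder
  # meets the inter-class valley
  # On log-counts the Gaussian background shoulder is a parabola with
  # constant negative curvature; its foot — where it meets the inter-class
  # valley — shows up as the first prominent positive-curvature peak after
  # the mode (later peaks belong to the foreground mode's feet).
  lsm <- log1p(pmax(sm, 0))
  i <- (mode_bin + 1):(n_bins - 1)
  curv <- lsm[i - 1] - 2 * lsm[i] + lsm[i + 1]
  is_loc_max <- curv >= c(curv[-1], -Inf) & curv >= c(-Inf, curv[-length(curv)])
  prominent <- which(is_loc_max & curv > 0 & curv >= 0.25 * max(curv))
  best <- if (length(prominent)) i[prominent[1]] else i[which.max(curv)]
  exp((br[best] + br[best + 1]) / 2)
}

# --- curvature-based splitting ----------------------------------------------

# Smoothed closed-contour curvature (rad/px); positive = convex.
contour_curvature <- function(xy, sigma = 2) {
  n <- nrow(xy)
  if (n < 8) return(rep(0, n))
  ksz <- ceiling(3 * sigma)
  kern <- stats::dnorm(seq(-ksz, ksz), sd = sigma)
  kern <- kern / sum(kern)
  smooth_circ <- function(z) {
    ext <- c(z[(n - ksz + 1):n], z, z[1:ksz])
    stats::filter(ext, kern, sides = 2)[(ksz + 1):(ksz + n)]
  }
  xs <- smooth_circ(xy[, 1]); ys <- smooth_circ(xy[, 2])
  dx <- (xs[c(2:n, 1)] - xs[c(n, 1:(n - 1))]) / 2
  dy <- (ys[c(2:n, 1)] - ys[c(n, 1:(n - 1))]) / 2
  theta <- atan2(dy, dx)
  dtheta <- diff(c(theta, theta[1]))
  dtheta <- (dtheta + pi) %% (2 * pi) - pi
  ds <- sqrt(dx^2 + dy^2)
  kappa <- dtheta / pmax(ds, 1e-6)
  # orient so that the total turning of a simple closed contour is +2*pi
  if (sum(dtheta) < 0) kappa <- -kappa
  kappa
}

#' Split touching nuclei along points of high perimeter concavity
#'
#' Objects larger than `reference_area_px` (typically the median object size)
#' are examined for concavity points — local maxima of negative perimeter
#' curvature beyond a concavity threshold. With two or more candidates, the
#' pair maximizing the ratio of perimeter distance to Euclidean distance is
#' chosen and the object is partitioned along the chord between them; the
#' procedure recurses on the fragments. Total foreground pixel count is
#' preserved (pixels are assigned to sides of the chord, none removed).
#'
#' @param mask integer label matrix.
#' @param reference_area_px area above which objects are checked (px^2).
#' @param concavity_threshold curvature below which a contour point is a
#'   split candidate (rad/px; negative).
#' @param min_area_px fragments smaller than this are not created.
#' @param contour_sigma Gaussian smoothing of the closed contour before
#'   curvature estimation (contour samples).
#' @return relabelled integer label matrix.
#' @export
split_touching_nuclei <- function(mask, reference_area_px,
                                  concavity_threshold = -0.15,
                                  min_area_px = 20, contour_sigma = 2) {
  if (reference_area_px <= 0) stopf("reference_area_px must be > 0")
  labels <- relabel_sequential(mask)
  repeat {
    areas <- tabulate(labels[labels > 0])
    big <- which(areas > reference_area_px & areas >= 2 * min_area_px)
    changed <- FALSE
    for (id in big) {
      parts <- try_split_object(labels == id, concavity_threshold, min_area_px,
                                contour_sigma)
      if (is.null(parts)) next
      new_id <- max(labels) + 1L
      sub <- labels
      sub[parts$b] <- new_id
      labels <- sub
      changed <- TRUE
    }
    if (!changed) break
  }
  relabel_sequential(labels)
}

# Attempt one split of a binary object; returns list(b = logical matrix of
# pixels reassigned to the new fragment) or NULL.
try_split_object <- function(obj, concavity_threshold, min_area_px,
                             contour_sigma = 2) {
  oc <- EBImage::ocontour(obj * 1)
  if (length(oc) == 0) return(NULL)
  xy <- oc[[1]]  # 0-based (row-1, col-1)
  n <- nrow(xy)
  if (n < 12) return(NULL)
  kappa <- contour_curvature(xy, sigma = contour_sigma)
  # local minima of curvature below the concavity threshold
  prev <- c(kappa[n], kappa[-n]); nxt <- c(kappa[-1], kappa[1])
  cand <- which(kappa < concavity_threshold & kappa <= prev & kappa <= nxt)
  if (length(cand) == 0) return(NULL)
  best <- NULL; best_ratio <- -Inf
  if (length(cand) >= 2) {
    # choose the pair maximizing perimeter distance / Euclidean distance
    for (a in seq_along(cand)) {
      for (b in seq_along(cand)) {
        if (b <= a) next
        i <- cand[a]; j <- cand[b]
        arc <- min(abs(i - j), n - abs(i - j))
        euc <- sqrt(sum((xy[i, ] - xy[j, ])^2))
        if (euc < 2) next
        ratio <- arc / euc
        if (ratio > best_ratio) { best_ratio <- ratio; best <- c(i, j) }
      }
    }
  }
  if (is.null(best) || best_ratio < 1.2) {
    # a lone concavity (e.g. after a previous cut consumed its partner):
    # cut to the nearest contour point on the far side of the waist
    i <- cand[which.min(kappa[cand])]
    far <- which(pmin(abs(seq_len(n) - i), n - abs(seq_len(n) - i)) >= n / 4)
    if (length(far) == 0) return(NULL)
    euc <- sqrt((xy[far, 1] - xy[i, 1])^2 + (xy[far, 2] - xy[i, 2])^2)
    j <- far[which.min(euc)]
    arc <- min(abs(i - j), n - abs(i - j))
    if (min(euc) < 2 || arc / min(euc) < 1.2) return(NULL)
    best <- c(i, j)
  }
  p1 <- xy[best[1], ]; p2 <- xy[best[2], ]
  idx <- which(obj, arr.ind = TRUE)
  # signed side of the chord (pixel coords are 1-based; contour 0-based)
  v <- p2 - p1
  s <- v[1] * ((idx[, 2] - 1) - p1[2]) - v[2] * ((idx[, 1] - 1) - p1[1])
  b_side <- s > 0
  if (sum(b_side) < min_area_px || sum(!b_side) < min_area_px) return(NULL)
  # both fragments must be coherent (single dominant component each)
  bmat <- matrix(FALSE, nrow(obj), ncol(obj))
  bmat[idx[b_side, , drop = FALSE]] <- TRUE
  list(b = bmat)
}

#' Segment nuclei in a fixed-cell DNA-stain image
#'
#' Histogram-curvature threshold, connected components, hole filling,
#' small-object removal, then curvature-based splitting of touching nuclei
#' using the median component area as the size reference.
#'
#' @param image flat-field-corrected DNA-stain image.
#' @param min_area_px minimum nucleus area (px^2).
#' @return integer label matrix.
#' @export
segment_fixed <- function(image, min_area_px = 40) {
  thr <- threshold_histogram_curvature(image)
  labels <- as.matrix(EBImage::bwlabel(EBImage::fillHull((image > thr) * 1)))
  storage.mode(labels) <- "integer"
  areas <- tabulate(labels[labels > 0])
  drop <- which(areas < min_area_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels <- relabel_sequential(labels)
  areas <- tabulate(labels[labels > 0])
  if (length(areas) == 0) return(labels)
  split_touching_nuclei(labels, reference_area_px = stats::median(areas),
                        min_area_px = min_area_px)
}
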