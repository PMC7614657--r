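# Internal helpers shared across modules.
#
# Image convention: a single-channel image is a plain numeric matrix indexed
# [row, col] = [y + 1, x + 1]; exported coordinates are 0-based (x, y), y-down,
# matching the ground-truth tables written by the simulator.

# disc-shaped structuring element of pixel radius r (odd-sized logical matrix)
disc_kernel <- function(r) {
  r <- max(1L, as.integer(round(r)))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

# Dilate a binary mask by a disc of radius r px.
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  EBImage::dilate(mask * 1, disc_kernel(r)) > 0
}

# Gaussian smoothing with linearly extrapolated (gradient-preserving)
# padding: plain mirror padding kinks the border gradient and biases smooth
# field-scale trends (such as an illumination profile) by several percent at
# the corners; odd extension about the edge value keeps the first-order
# behaviour intact.
gauss_smooth_mirror <- function(img, sigma) {
  if (sigma <= 0) return(img)
  pad <- ceiling(3 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  pad_r <- min(pad, nr - 1L); pad_c <- min(pad, nc - 1L)
  top <- 2 * img[rep(1L, pad_r), , drop = FALSE] -
    img[(pad_r + 1L):2, , drop = FALSE]
  bot <- 2 * img[rep(nr, pad_r), , drop = FALSE] -
    img[(nr - 1L):(nr - pad_r), , drop = FALSE]
  ext <- rbind(top, img, bot)
  left <- 2 * ext[, rep(1L, pad_c), drop = FALSE] -
    ext[, (pad_c + 1L):2, drop = FALSE]
  right <- 2 * ext[, rep(ncol(ext), pad_c), drop = FALSE] -
    ext[, (ncol(ext) - 1L):(ncol(ext) - pad_c), drop = FALSE]
  ext <- cbind(left, ext, right)
  sm <- EBImage::gblur(ext, sigma = sigma)
  sm[(pad_r + 1L):(pad_r + nr), (pad_c + 1L):(pad_c + nc)]
}

# Separable cubic-convolution (Catmull-Rom, a = -0.5) upsampling by an integer
# factor; used to bring live-cell images to the fixed-cell pixel grid.
bicubic_upsample <- function(img, k) {
  k <- as.integer(k)
  if (k == 1L) return(img)
  cubic <- function(s, a = -0.5) {
    s <- abs(s)
    ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
           ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
  }
  up1 <- function(m, k) {
    n <- nrow(m)
    # output row i (1-based) samples source position (i - 0.5) / k + 0.5
    pos <- (seq_len(n * k) - 0.5) / k + 0.5
    i0 <- floor(pos)
    frac <- pos - i0
    out <- matrix(0, n * k, ncol(m))
    for (t in -1:2) {
      idx <- pmin(pmax(i0 + t, 1L), n)
      w <- cubic(t - frac)
      out <- out + w * m[idx, , drop = FALSE]
    }
    out
  }
  t(up1(t(up1(img, k)), k))
}

# Mean-value binning by an integer factor (block average).
bin_mean <- function(img, k) {
  k <- as.integer(k)
  if (k == 1L) return(img)
  nr <- (nrow(img) %/% k) * k
  nc <- (ncol(img) %/% k) * k
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(img, dim = c(k, nr %/% k, k, nc %/% k))
  apply(a, c(2, 4), mean)
}

# Per-label centroids of a label matrix, returned 0-based (x, y).
label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0)
    return(data.frame(label = integer(), x = numeric(), y = numeric(),
                      area = integer()))
  idx <- which(labels > 0)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  data.frame(
    label = ids,
    x = tapply(cc - 1, lab, mean)[as.character(ids)],
    y = tapply(rr - 1, lab, mean)[as.character(ids)],
    area = as.integer(table(lab)[as.character(ids)]),
    row.names = NULL
  )
}

# Grayscale morphological top-hat in counts. EBImage grayscale morphology
# assumes intensities in [0, 1], so scale there and back.
tophat_gray <- function(img, radius) {
  mx <- max(img)
  if (mx <= 0) return(img * 0)
  as.matrix(EBImage::whiteTopHat(img / mx, disc_kernel(radius))) * mx
}

# Mean-1 lognormal deviates with coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Lognormal deviates with given median and cv (phase durations).
rlnorm_med_cv <- function(n, median, cv) {
  if (cv <= 0) return(rep(median, n))
  stats::rlnorm(n, meanlog = log(median), sdlog = sqrt(log(1 + cv^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
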