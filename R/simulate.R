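# Synthetic-microscopy generator: ground-truthed populations of moving,
# dividing nuclei carrying cell-cycle reporter kinetics, rendered into live
# movies and end-point fixed snapshots with a configurable camera model.

# Evaluate code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a ground-truthed cell population
#'
#' Cells move by an isotropic Gaussian random walk, progress through
#' lognormally distributed G1/S/G2M phases, and divide at the end of G2M into
#' two daughters placed adjacent to the parent. Reporter traces follow the
#' kinetics the pipeline is designed to detect: the CRL4-Cdt2 reporter rises
#' linearly from anaphase and decays exponentially from S entry; the
#' APC/C-Cdh1 reporter stays near zero until APC/C inactivation then rises
#' linearly; endogenous-CDT1 immunofluorescence decays exponentially from S
#' entry; PCNA foci area is ~0 outside S phase and ramps to a plateau after S
#' entry; EdU equals the Hill model evaluated at the cell's ND-CDT1 level for
#' cells in S at movie end and is ~0 otherwise.
#'
#' @param config a [sim_config()].
#' @param programmed optional data frame overriding founder cells; columns
#'   among `birth_time`, `g1`, `s`, `g2m`, `x`, `y`, `ndcdt1` (row i applies
#'   to founder i).
#' @return An object of class `"sim_population"`: list with `cells` (one row
#'   per cell: lineage, event times in minutes — `NA` when outside the movie —
#'   expression levels, ground-truth EdU) and `frames` (one row per cell per
#'   frame: 0-based centroids, true area, per-channel trace values).
#' @export
simulate_population <- function(config, programmed = NULL) {
  cfg <- validate_sim_config(config)
  with_seed(cfg$seed, simulate_population_impl(cfg, programmed))
}

simulate_population_impl <- function(cfg, programmed) {
  dims <- cfg$field_size_px
  movie_end <- (cfg$n_frames - 1L) * cfg$frame_interval_min
  rk <- cfg$reporter_kinetics
  ccp <- cfg$cell_cycle_params
  r_range_px <- sort(cfg$nucleus_radius_um / cfg$pixel_size_um)
  r_max <- r_range_px[2]

  draw_durations <- function() c(
    g1 = rlnorm_med_cv(1, ccp$g1[[1]], ccp$g1[[2]]),
    s = rlnorm_med_cv(1, ccp$s[[1]], ccp$s[[2]]),
    g2m = rlnorm_med_cv(1, ccp$g2m[[1]], ccp$g2m[[2]])
  )

  # founders: random cycle positions and well-spread initial placements
  founders <- vector("list", cfg$n_cells_initial)
  placed <- matrix(NA_real_, 0, 2)
  for (i in seq_len(cfg$n_cells_initial)) {
    dur <- draw_durations()
    age <- stats::runif(1, 0, sum(dur))
    pos <- NULL
    for (try in 1:60) {
      cand <- c(stats::runif(1, r_max, dims[2] - 1 - r_max),
                stats::runif(1, r_max, dims[1] - 1 - r_max))
      if (nrow(placed) == 0 ||
          min(sqrt(colSums((t(placed) - cand)^2))) > 1.8 * r_max) {
        pos <- cand; break
      }
    }
    if (is.null(pos)) pos <- cand
    placed <- rbind(placed, pos)
    founders[[i]] <- list(birth_time = -age, dur = dur, pos0 = pos,
                          ndcdt1 = exp(stats::runif(1, log(cfg$ndcdt1_range[1]),
                                                    log(cfg$ndcdt1_range[2]))),
                          h2b_total = stats::rlnorm(1, log(20000), 0.2),
                          crl4_expr = rlnorm_cv(1, 0.2),
                          apcc_expr = rlnorm_cv(1, 0.2),
                          cdt1_expr = rlnorm_cv(1, 0.2),
                          radius_px = stats::runif(1, r_range_px[1], r_range_px[2]))
  }
  if (!is.null(programmed)) {
    for (i in seq_len(min(nrow(programmed), length(founders)))) {
      p <- programmed[i, , drop = FALSE]
      if (!is.null(p$birth_time)) founders[[i]]$birth_time <- p$birth_time
      for (ph in c("g1", "s", "g2m"))
        if (!is.null(p[[ph]])) founders[[i]]$dur[[ph]] <- p[[ph]]
      if (!is.null(p$x)) founders[[i]]$pos0[1] <- p$x
      if (!is.null(p$y)) founders[[i]]$pos0[2] <- p$y
      if (!is.null(p$ndcdt1)) founders[[i]]$ndcdt1 <- p$ndcdt1
    }
  }

  cells <- list(); frames <- list()
  meta <- list()   # placement info per cell for the motion pass
  queue <- founders
  for (i in seq_along(queue)) queue[[i]]$parent_id <- NA_integer_
  next_id <- 1L
  while (length(queue) > 0) {
    cell <- queue[[1]]; queue <- queue[-1]
    id <- next_id; next_id <- next_id + 1L
    dur <- cell$dur
    birth <- cell$birth_time
    division <- birth + sum(dur)
    s_entry <- birth + dur[["g1"]]
    lead <- rlnorm_med_cv(1, rk$apcc_lead_min[[1]], rk$apcc_lead_min[[2]])
    apcc_t <- max(s_entry - lead, birth + 0.1 * dur[["g1"]])
    cdt1_deg <- s_entry + rk$cdt1_if_half_min * log2(1 / rk$degraded_gate_frac)

    fidx <- seq(0L, cfg$n_frames - 1L)
    t_f <- fidx * cfg$frame_interval_min
    alive <- t_f >= birth & t_f < division
    if (division >= movie_end) alive <- t_f >= birth   # survives to movie end
    fidx <- fidx[alive]; t_f <- t_f[alive]
    n_al <- length(fidx)

    # reporter kinetics along the cell's own lifetime
    crl4 <- crl4_trace(t_f, birth, s_entry, cell$crl4_expr, rk$crl4_decay_half_min)
    apcc <- apcc_trace(t_f, apcc_t, cell$apcc_expr, rk$apcc_rise_per_min)
    s_end <- s_entry + dur[["s"]]
    cdt1 <- cdt1_if_trace(t_f, s_entry, s_end, division, cell$cdt1_expr,
                          rk$cdt1_if_half_min)
    gmn <- gmn_trace(t_f, apcc_t, cell$cdt1_expr, rk$gmn_rise_per_min)
    foci <- foci_trace(t_f, s_entry, s_end, rk$foci_peak_px, rk$foci_ramp_min)
    dna <- dna_content(t_f, s_entry, s_end)

    in_s_at_end <- movie_end >= s_entry && movie_end < s_end && division > movie_end
    edu <- if (in_s_at_end) hill_response(cell$ndcdt1, cfg$hill_params) else 0.05

    clamp_na <- function(t) if (!is.na(t) && t >= 0 && t <= movie_end) t else NA_real_
    cells[[id]] <- data.frame(
      cell_id = id, parent_id = cell$parent_id,
      anaphase_time = clamp_na(birth),
      apcc_inactivation_time = clamp_na(apcc_t),
      s_entry_time = clamp_na(s_entry),
      cdt1_fully_degraded_time = clamp_na(cdt1_deg),
      division_time = if (division < movie_end) division else NA_real_,
      birth_abs = birth, s_entry_abs = s_entry, s_end_abs = s_end,
      apcc_abs = apcc_t, division_abs = division,
      radius_px = cell$radius_px, h2b_total = cell$h2b_total,
      ndcdt1 = cell$ndcdt1, edu = edu, in_s_at_end = in_s_at_end
    )
    meta[[id]] <- list(pos0 = cell$pos0, parent = cell$parent_id,
                       first = if (n_al) fidx[1] else NA_integer_,
                       radius = cell$radius_px)
    if (n_al > 0)
      frames[[id]] <- data.frame(
        cell_id = id, frame = fidx, time_min = t_f,
        x = NA_real_, y = NA_real_,
        radius_px = cell$radius_px,
        area_px = pi * cell$radius_px^2,
        H2B = cell$h2b_total, CRL4 = crl4, APCC = apcc,
        CDT1IF = cdt1, GMNNIF = gmn, PCNAFOCI = foci, DNA = dna
      )

    if (division < movie_end) {
      frac <- min(max(stats::rnorm(1, 0.5, 0.02), 0.42), 0.58)
      for (k in 1:2) {
        queue[[length(queue) + 1L]] <- list(
          birth_time = division, dur = draw_durations(), pos0 = NULL,
          ndcdt1 = cell$ndcdt1, parent_id = id,
          h2b_total = cell$h2b_total * (if (k == 1) frac else 1 - frac),
          crl4_expr = cell$crl4_expr * rlnorm_cv(1, 0.05),
          apcc_expr = cell$apcc_expr * rlnorm_cv(1, 0.05),
          cdt1_expr = cell$cdt1_expr * rlnorm_cv(1, 0.05),
          radius_px = cell$radius_px
        )
      }
    }
  }

  frames <- do.call(rbind, frames)
  frames <- simulate_motion(frames, meta, cfg, r_max)

  structure(list(cells = do.call(rbind, cells),
                 frames = frames,
                 config = cfg),
            class = "sim_population")
}

# Frame-synchronized motion: cells step by an isotropic Gaussian walk, and
# pairs closer than exclusion_frac x (r_i + r_j) are relaxed apart, so
# nuclei touch but do not interpenetrate. Daughters appear adjacent to the
# parent's last position on opposite sides.
simulate_motion <- function(frames, meta, cfg, r_max) {
  dims <- cfg$field_size_px
  sigma <- cfg$motion_sigma_px_per_frame
  excl <- cfg$exclusion_frac %||% 0
  pos <- vector("list", length(meta))  # cell_id -> c(x, y), current frame
  dtheta <- list()   # parent id (character) -> first daughter's direction
  ord <- order(frames$frame, frames$cell_id)
  frames <- frames[ord, ]
  row_of <- split(seq_len(nrow(frames)), frames$frame)
  for (fch in as.character(sort(unique(frames$frame)))) {
    rows <- row_of[[fch]]
    ids <- frames$cell_id[rows]
    # step cells already present; place the ones appearing this frame
    for (i in seq_along(ids)) {
      id <- ids[i]
      if (!is.null(pos[[id]])) {
        pos[[id]] <- pos[[id]] + stats::rnorm(2, 0, sigma)
      } else {
        m <- meta[[id]]
        if (!is.na(m$parent) && !is.null(pos[[m$parent]])) {
          key <- as.character(m$parent)
          # the two daughters take opposite sides of the parent centroid
          if (is.null(dtheta[[key]])) {
            theta <- stats::runif(1, 0, 2 * pi)
            dtheta[[key]] <- theta
            side <- 1
          } else {
            theta <- dtheta[[key]]
            side <- -1
          }
          pos[[id]] <- pos[[m$parent]] +
            side * m$radius * c(cos(theta), sin(theta))
        } else if (!is.null(m$pos0)) {
          pos[[id]] <- m$pos0
        } else {
          pos[[id]] <- c(stats::runif(1, r_max, dims[2] - 1 - r_max),
                         stats::runif(1, r_max, dims[1] - 1 - r_max))
        }
      }
    }
    # drop parents that disappeared (divided) from the active set
    # pairwise exclusion relaxation
    P <- do.call(rbind, pos[ids])
    radii <- vapply(ids, function(id) meta[[id]]$radius, 0)
    if (excl > 0 && length(ids) > 1) {
      for (it in 1:6) {
        dx <- outer(P[, 1], P[, 1], `-`)
        dy <- outer(P[, 2], P[, 2], `-`)
        d <- sqrt(dx^2 + dy^2)
        dmin <- excl * outer(radii, radii, `+`)
        viol <- which(d < dmin & upper.tri(d), arr.ind = TRUE)
        if (nrow(viol) == 0) break
        for (v in seq_len(nrow(viol))) {
          i <- viol[v, 1]; j <- viol[v, 2]
          delta <- P[i, ] - P[j, ]
          dd <- sqrt(sum(delta^2))
          u <- if (dd < 1e-6) {
            th <- stats::runif(1, 0, 2 * pi); c(cos(th), sin(th))
          } else delta / dd
          push <- (dmin[i, j] - dd) / 2
          P[i, ] <- P[i, ] + u * push
          P[j, ] <- P[j, ] - u * push
        }
      }
    }
    P[, 1] <- reflect_into(P[, 1], r_max, dims[2] - 1 - r_max)
    P[, 2] <- reflect_into(P[, 2], r_max, dims[1] - 1 - r_max)
    for (i in seq_along(ids)) pos[[ids[i]]] <- P[i, ]
    frames$x[rows] <- P[, 1]
    frames$y[rows] <- P[, 2]
  }
  frames
}

reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  lo + ifelse(x > span, 2 * span - x, x)
}

# --- reporter kinetics -------------------------------------------------------

crl4_trace <- function(t, anaphase, s_entry, expr, half_min) {
  rise <- pmax(0, pmin(1, (t - anaphase) / max(s_entry - anaphase, 1)))
  out <- expr * rise
  post <- t >= s_entry
  out[post] <- expr * 2^(-(t[post] - s_entry) / half_min)
  pmax(out, 0)
}

apcc_trace <- function(t, apcc_t, expr, rise_per_min) {
  base <- 0.02 * expr
  out <- rep(base, length(t))
  post <- t >= apcc_t
  out[post] <- base + expr * rise_per_min * (t[post] - apcc_t)
  out
}

cdt1_if_trace <- function(t, s_entry, s_end, division, expr, half_min) {
  out <- rep(expr, length(t))
  in_s <- t >= s_entry
  out[in_s] <- expr * 2^(-(t[in_s] - s_entry) / half_min)
  g2 <- t >= s_end
  if (any(g2)) {
    low <- expr * 2^(-(s_end - s_entry) / half_min)
    g2_len <- max(division - s_end, 1)
    out[g2] <- low + (expr - low) * pmin(1, (t[g2] - s_end) / g2_len)
  }
  pmax(out, 0)
}

gmn_trace <- function(t, apcc_t, expr, rise_per_min) {
  pmax(0, expr * rise_per_min * (t - apcc_t))
}

foci_trace <- function(t, s_entry, s_end, peak_px, ramp_min) {
  in_s <- t >= s_entry & t < s_end
  out <- numeric(length(t))
  out[in_s] <- peak_px * pmin(1, (t[in_s] - s_entry) / ramp_min)
  out
}

dna_content <- function(t, s_entry, s_end) {
  pmin(2, pmax(1, 1 + (t - s_entry) / max(s_end - s_entry, 1)))
}

# --- rendering ---------------------------------------------------------------

# Add a truncated-Gaussian nuclear blob (total intensity = total) in place.
add_blob <- function(img, x, y, radius_px, total) {
  sigma <- radius_px / 2.5
  r_ceil <- ceiling(radius_px)
  rows <- max(1L, floor(y + 1 - r_ceil)):min(nrow(img), ceiling(y + 1 + r_ceil))
  cols <- max(1L, floor(x + 1 - r_ceil)):min(ncol(img), ceiling(x + 1 + r_ceil))
  if (length(rows) == 0 || length(cols) == 0) return(img)
  dy <- rows - 1 - y; dx <- cols - 1 - x
  d2 <- outer(dy^2, dx^2, `+`)
  g <- exp(-d2 / (2 * sigma^2))
  g[d2 > radius_px^2] <- 0
  s <- sum(g)
  if (s > 0) img[rows, cols] <- img[rows, cols] + g * (total / s)
  img
}

# Ground-truth label map: pixels within each nucleus radius, ties to the
# nearer centre.
truth_label_map <- function(df, dims) {
  labels <- matrix(0L, dims[1], dims[2])
  bestd <- matrix(Inf, dims[1], dims[2])
  for (i in seq_len(nrow(df))) {
    x <- df$x[i]; y <- df$y[i]; r <- df$radius_px[i]
    r_ceil <- ceiling(r)
    rlo <- max(1L, floor(y + 1 - r_ceil)); rhi <- min(dims[1], ceiling(y + 1 + r_ceil))
    clo <- max(1L, floor(x + 1 - r_ceil)); chi <- min(dims[2], ceiling(x + 1 + r_ceil))
    if (rlo > rhi || clo > chi) next   # entirely outside the field
    rows <- rlo:rhi; cols <- clo:chi
    d2 <- outer((rows - 1 - y)^2, (cols - 1 - x)^2, `+`)
    sel <- d2 <= r^2 & d2 < bestd[rows, cols]
    sub_l <- labels[rows, cols]; sub_d <- bestd[rows, cols]
    sub_l[sel] <- df$cell_id[i]; sub_d[sel] <- d2[sel]
    labels[rows, cols] <- sub_l; bestd[rows, cols] <- sub_d
  }
  labels
}

# Deterministic in-nucleus punctum positions for a cell (unit-disc coords).
focus_positions <- function(cell_id, n_max = 60L, seed_base = 7L) {
  with_seed(seed_base + 131L * cell_id, {
    th <- stats::runif(n_max, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_max)) * 0.7
    cbind(rad * cos(th), rad * sin(th))
  })
}

#' Render a simulated population into per-channel live-movie stacks
#'
#' Nuclei are drawn as isotropic Gaussian blobs truncated at the nuclear
#' radius (2.5 sigma), scaled so the integrated intensity equals the cell's
#' trace value; H2B intensity is conserved across frames and split between
#' daughters at division. The PCNA-foci channel adds bright punctate spots
#' inside S-phase nuclei. The camera model is *not* applied; see
#' [apply_camera_model()].
#'
#' @param population a [simulate_population()] result.
#' @param config the same [sim_config()].
#' @param channels channel names to render (subset of `H2B`, `CRL4`, `APCC`,
#'   `PCNAFOCI`).
#' @return list with `stacks` (named list of per-frame matrices, signal in
#'   counts), `truth` (per cell per frame table with the per-channel rendered
#'   totals), and `masks` (per-frame ground-truth label maps).
#' @export
render_movie <- function(population, config,
                         channels = c("H2B", "CRL4", "APCC", "PCNAFOCI")) {
  cfg <- validate_sim_config(config)
  fr <- population$frames
  stacks <- lapply(channels, function(ch) vector("list", cfg$n_frames))
  names(stacks) <- channels
  masks <- vector("list", cfg$n_frames)
  for (f in seq(0L, cfg$n_frames - 1L)) {
    rf <- render_live_frame(population, cfg, f, channels)
    masks[[f + 1L]] <- rf$mask
    for (ch in channels) stacks[[ch]][[f + 1L]] <- rf$images[[ch]]
  }
  list(stacks = stacks, truth = fr, masks = masks)
}

# Render one live frame (signal only); shared by render_movie and the
# streaming pipeline.
render_live_frame <- function(population, cfg, f,
                              channels = c("H2B", "CRL4", "APCC", "PCNAFOCI")) {
  dims <- cfg$field_size_px
  sub <- population$frames[population$frames$frame == f, , drop = FALSE]
  bg <- cfg$camera$background_au %||% 0
  gains <- c(CRL4 = 15000, APCC = 15000)
  images <- lapply(channels, function(ch) {
    tot <- switch(ch,
      H2B = sub$H2B,
      CRL4 = sub$CRL4 * gains[["CRL4"]],
      APCC = sub$APCC * gains[["APCC"]],
      PCNAFOCI = rep(3000, nrow(sub)))
    img <- add_blobs_cpp(dims[1], dims[2], bg, sub$x, sub$y,
                         sub$radius_px, tot)
    if (ch == "PCNAFOCI") img <- add_foci(img, sub)
    img
  })
  names(images) <- channels
  list(images = images, mask = truth_label_map(sub, dims), truth = sub)
}

# radius per frame row comes from the cells table; attach it up front
#' @noRd
add_foci <- function(img, sub) {
  for (i in seq_len(nrow(sub))) {
    n_foci <- round(sub$PCNAFOCI[i] / 4)
    if (n_foci <= 0) next
    posu <- focus_positions(sub$cell_id[i])
    n_foci <- min(n_foci, nrow(posu))
    r <- sub$radius_px[i]
    for (j in seq_len(n_foci)) {
      fx <- sub$x[i] + posu[j, 1] * r
      fy <- sub$y[i] + posu[j, 2] * r
      rows <- (floor(fy) + 1L):(floor(fy) + 2L)
      cols <- (floor(fx) + 1L):(floor(fx) + 2L)
      rows <- rows[rows >= 1 & rows <= nrow(img)]
      cols <- cols[cols >= 1 & cols <= ncol(img)]
      img[rows, cols] <- img[rows, cols] + 200
    }
  }
  img
}

#' Apply the camera model to a rendered signal image
#'
#' The detector reports `offset + profile * (signal + bleedthrough) + noise`:
#' a constant camera offset, multiplicative shading by a smooth illumination
#' profile, additive spectral bleedthrough from co-acquired channels, and
#' Gaussian read noise plus a Poisson-like variance term proportional to the
#' signal. With noise disabled the mapping is exactly inverted by
#' [flatfield_correct()] and [correct_bleedthrough()].
#'
#' @param image signal image (matrix, counts).
#' @param config a [sim_config()]; its `camera` entry supplies offset,
#'   illumination, noise and bleedthrough parameters.
#' @param channel name of this channel (for bleedthrough lookup).
#' @param sources named list of co-acquired *signal* images bleeding into
#'   this channel (bleedthrough keys are `"<from>_<into>"`).
#' @param noise logical; disable for exactly invertible output.
#' @return the detected image (matrix, counts).
#' @export
apply_camera_model <- function(image, config, channel = NULL,
                               sources = list(), noise = TRUE) {
  cfg <- validate_sim_config(config)
  offset <- cfg$camera$offset %||% 0
  prof <- illumination_field(cfg)
  if (!all(dim(prof) == dim(image)))
    prof <- matrix(1, nrow(image), ncol(image))
  sig <- image
  bt <- cfg$camera$bleedthrough %||% list()
  if (length(sources) && length(bt) && !is.null(channel)) {
    for (from in names(sources)) {
      key <- paste0(from, "_", channel)
      if (!is.null(bt[[key]])) sig <- sig + bt[[key]] * sources[[from]]
    }
  }
  out <- offset + prof * sig
  if (noise) {
    v <- (cfg$camera$read_noise_sd %||% 0)^2 +
      (cfg$camera$shot_scale %||% 0) * pmax(sig, 0)
    out <- out + matrix(stats::rnorm(length(out), 0, sqrt(v)),
                        nrow(out), ncol(out))
  }
  out
}

#' Render the end-point fixed-cell snapshot
#'
#' Renders DNA stain, endogenous-CDT1, geminin-like and ND-CDT1
#' immunofluorescence, and EdU at the final movie time, optionally at a finer
#' pixel size (magnification ratio >= 1) and with a whole-field translation
#' (the plate is replaced on the stage between live imaging and fixed
#' imaging). Fixed-frame centroid = ratio * live centroid + offset.
#'
#' @param population a [simulate_population()] result.
#' @param config the same [sim_config()]; `config$fixed` gives
#'   `magnification_ratio` and `offset_px` (x, y).
#' @return list with `images` (named matrices: DNA, CDT1IF, GMNNIF, EDU,
#'   NDCDT1IF), `truth` (per-cell table with fixed-frame centroids and true
#'   values), and `mask` (ground-truth label map in the fixed frame).
#' @export
render_fixed_snapshot <- function(population, config) {
  cfg <- validate_sim_config(config)
  ratio <- cfg$fixed$magnification_ratio %||% 1
  if (ratio < 1) stopf("magnification ratio must be >= 1")
  off <- cfg$fixed$offset_px %||% c(0, 0)
  dims <- as.integer(round(cfg$field_size_px * ratio))
  last_f <- cfg$n_frames - 1L
  fr <- population$frames
  sub <- fr[fr$frame == last_f, , drop = FALSE]
  cells <- population$cells
  sub <- merge(sub, cells[, c("cell_id", "ndcdt1", "edu")], by = "cell_id")
  sub$x_fix <- sub$x * ratio + off[1]
  sub$y_fix <- sub$y * ratio + off[2]
  sub$radius_fix <- sub$radius_px * ratio
  gains <- c(DNA = 10000, CDT1IF = 15000, GMNNIF = 15000, EDU = 1000,
             NDCDT1IF = 1000)
  totals <- list(DNA = sub$DNA * gains[["DNA"]],
                 CDT1IF = sub$CDT1IF * gains[["CDT1IF"]],
                 GMNNIF = sub$GMNNIF * gains[["GMNNIF"]],
                 EDU = sub$edu * gains[["EDU"]],
                 NDCDT1IF = sub$ndcdt1 * gains[["NDCDT1IF"]])
  bg <- cfg$camera$background_au %||% 0
  images <- lapply(names(totals), function(ch)
    add_blobs_cpp(dims[1], dims[2], bg, sub$x_fix, sub$y_fix,
                  sub$radius_fix, totals[[ch]]))
  names(images) <- names(totals)
  mdf <- data.frame(cell_id = sub$cell_id, x = sub$x_fix, y = sub$y_fix,
                    radius_px = sub$radius_fix)
  truth <- data.frame(cell_id = sub$cell_id,
                      x_live = sub$x, y_live = sub$y,
                      x = sub$x_fix, y = sub$y_fix,
                      radius_px = sub$radius_fix,
                      dna = sub$DNA, cdt1_if = sub$CDT1IF,
                      gmn_if = sub$GMNNIF, edu = sub$edu,
                      ndcdt1 = sub$ndcdt1)
  list(images = images, truth = truth,
       mask = truth_label_map(mdf, dims))
}

#' Sample a synthetic single-cell dose-response table
#'
#' ND-CDT1 levels are drawn log-uniformly over `expression_range`; EdU is the
#' Hill-model response multiplied by mean-1 lognormal noise with coefficient
#' of variation `noise_cv`, floored at zero. Optionally appends ND-CDT1
#' negative cells (`ndcdt1 = 0`, EdU scattered around `edu_max`), which
#' downstream fitting uses to fix the EdU ceiling.
#'
#' @param fit a [hill_params()] set (or `"hill_fit"` object) generating EdU.
#' @param n number of expressing cells (>= 10).
#' @param noise_cv multiplicative noise CV (>= 0).
#' @param expression_range length-2 positive range of ND-CDT1 (a.u.).
#' @param seed integer seed.
#' @param n_negative number of ND-CDT1-negative cells to append.
#' @return data frame with columns `ndcdt1`, `edu`.
#' @examples
#' hp <- hill_params(22, 1, 10.2, 4.2)
#' d <- sample_dose_response(hp, 500, noise_cv = 0, c(0.5, 40), seed = 1)
#' @export
sample_dose_response <- function(fit, n, noise_cv, expression_range, seed,
                                 n_negative = 0L) {
  if (n < 10) stopf("n must be >= 10")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  if (any(expression_range <= 0)) stopf("expression_range must be positive")
  p <- as_hill_params(fit)
  with_seed(seed, {
    x <- exp(stats::runif(n, log(expression_range[1]), log(expression_range[2])))
    edu <- pmax(0, hill_response(x, p) * rlnorm_cv(n, noise_cv))
    out <- data.frame(ndcdt1 = x, edu = edu)
    if (n_negative > 0) {
      neg <- data.frame(ndcdt1 = 0,
                        edu = pmax(0, p$edu_max * rlnorm_cv(n_negative, noise_cv)))
      out <- rbind(out, neg)
    }
    out
  })
}
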