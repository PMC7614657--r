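#' Hill dose-response parameter set
#'
#' Bundles the four parameters of the sigmoidal EdU dose-response
#' \deqn{EdU(x) = EdU_{max} - \frac{EdU_{max}-EdU_{min}}{1 + (IC_{50}/x)^n}}
#' used both to generate synthetic single-cell data and as the target of
#' [fit_hill()].
#'
#' @param edu_max EdU incorporation of cells without the inhibitor (a.u.).
#' @param edu_min minimum EdU incorporation at saturating inhibitor (a.u.).
#' @param ic50 half-inhibitory inhibitor level (a.u., > 0).
#' @param n_hill Hill coefficient (> 0).
#' @return A list of class `"hill_params"`.
#' @examples
#' hp <- hill_params(22, 1, 10.2, 4.2)
#' hill_response(hp$ic50, hp)  # midpoint: (22 + 1) / 2
#' @export
hill_params <- function(edu_max, edu_min, ic50, n_hill) {
  if (ic50 <= 0) stopf("ic50 must be > 0")
  if (n_hill <= 0) stopf("n_hill must be > 0")
  if (edu_min > edu_max) stopf("edu_min must be <= edu_max")
  structure(list(edu_max = edu_max, edu_min = edu_min,
                 ic50 = ic50, n_hill = n_hill),
            class = "hill_params")
}

#' Evaluate the Hill dose-response curve
#'
#' @param x inhibitor level (a.u.); `x = 0` returns `edu_max` (the limit).
#' @param params a [hill_params()] list or a fitted `"hill_fit"` object.
#' @return EdU values, same length as `x`.
#' @export
hill_response <- function(x, params) {
  p <- as_hill_params(params)
  out <- p$edu_max - (p$edu_max - p$edu_min) / (1 + (p$ic50 / x)^p$n_hill)
  out[x == 0] <- p$edu_max
  out
}

as_hill_params <- function(p) {
  if (inherits(p, "hill_fit")) {
    cf <- p$params
    return(hill_params(cf[["edu_max"]], cf[["edu_min"]],
                       cf[["ic50"]], cf[["n_hill"]]))
  }
  if (inherits(p, "hill_params")) return(p)
  if (is.list(p) && all(c("edu_max", "edu_min", "ic50", "n_hill") %in% names(p)))
    return(hill_params(p$edu_max, p$edu_min, p$ic50, p$n_hill))
  stopf("cannot interpret object as Hill parameters")
}

#' Simulation configuration for the synthetic-microscopy generator
#'
#' Defines the study conditions the generator emulates: field geometry, frame
#' timing, nuclear motion and size, per-phase cell-cycle duration
#' distributions, reporter kinetics, the Hill model driving EdU, and the
#' camera model (offset, illumination profile, noise, bleedthrough).
#'
#' Coordinates are 0-based pixel indices, y-down; centroids are floats; times
#' are minutes from movie start. Frame `t` is acquired at `t *
#' frame_interval_min` (frame indices 0-based).
#'
#' @param field_size_px integer pair (rows, cols); each side >= 64.
#' @param pixel_size_um microns per pixel of the live movie.
#' @param frame_interval_min minutes between frames.
#' @param n_frames number of live frames.
#' @param n_cells_initial cells seeded at frame 0.
#' @param motion_sigma_px_per_frame isotropic Gaussian step sd (px/frame);
#'   must stay below the nucleus radius in px.
#' @param exclusion_frac nuclei are relaxed apart when closer than this
#'   fraction of their summed radii (0 disables the exclusion); models the
#'   fact that interphase nuclei in a monolayer touch but do not
#'   interpenetrate.
#' @param nucleus_radius_um length-2 range of nuclear radii (um).
#' @param cell_cycle_params list of per-phase duration distributions, each
#'   `c(median, cv)` in minutes: `g1`, `s`, `g2m`.
#' @param reporter_kinetics list: `crl4_decay_half_min` (CRL4-Cdt2 reporter
#'   degradation half-time after S entry), `cdt1_if_half_min` (endogenous
#'   CDT1 immunofluorescence half-time), `degraded_gate_frac` (fraction of the
#'   pre-S level below which a cell counts as fully degraded),
#'   `apcc_lead_min` `c(median, cv)` (lead of APC/C-Cdh1 inactivation over S
#'   entry), `apcc_rise_per_min` and `gmn_rise_per_min` (linear ramp rates as
#'   fraction of expression per minute), `foci_peak_px` and
#'   `foci_ramp_min` (PCNA foci-area plateau and ramp time).
#' @param hill_params a [hill_params()] set generating EdU from ND-CDT1.
#' @param ndcdt1_range length-2 range (a.u.); per-cell ND-CDT1 expression is
#'   drawn log-uniformly over it.
#' @param camera list: `offset` (counts), `illumination` (`"flat"`,
#'   `"gaussian"` or a matrix), `illumination_amplitude` (peak-to-edge falloff
#'   of the Gaussian profile), `read_noise_sd`, `shot_scale` (variance per
#'   unit signal for the Poisson-like term; 0 disables), `bleedthrough`
#'   (named list `from_to = coefficient`), `background_au` (uniform
#'   autofluorescence signal level).
#' @param fixed list describing the end-point snapshot: `magnification_ratio`
#'   (>= 1), `offset_px` integer pair (whole-field translation, fixed-frame
#'   px).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(field_size_px = c(640L, 640L),
                       pixel_size_um = 0.65,
                       frame_interval_min = 12,
                       n_frames = 120L,
                       n_cells_initial = 50L,
                       motion_sigma_px_per_frame = 1.5,
                       exclusion_frac = 0.7,
                       nucleus_radius_um = c(4.2, 5.4),
                       cell_cycle_params = list(
                         g1 = c(median = 540, cv = 0.25),
                         s = c(median = 540, cv = 0.15),
                         g2m = c(median = 300, cv = 0.2)
                       ),
                       reporter_kinetics = list(
                         crl4_decay_half_min = 8,
                         cdt1_if_half_min = 9,
                         degraded_gate_frac = 0.1,
                         apcc_lead_min = c(median = 30, cv = 0.3),
                         apcc_rise_per_min = 1 / 180,
                         gmn_rise_per_min = 1 / 240,
                         foci_peak_px = 120,
                         foci_ramp_min = 30
                       ),
                       hill_params = rtqibc::hill_params(22, 1, 10.2, 4.2),
                       ndcdt1_range = c(0.5, 40),
                       camera = list(
                         offset = 100,
                         illumination = "gaussian",
                         illumination_amplitude = 0.25,
                         read_noise_sd = 2,
                         shot_scale = 0.5,
                         bleedthrough = list(),
                         background_au = 20
                       ),
                       fixed = list(magnification_ratio = 2,
                                    offset_px = c(0L, 0L)),
                       seed = 1L) {
  cfg <- list(field_size_px = as.integer(field_size_px),
              pixel_size_um = pixel_size_um,
              frame_interval_min = frame_interval_min,
              n_frames = as.integer(n_frames),
              n_cells_initial = as.integer(n_cells_initial),
              motion_sigma_px_per_frame = motion_sigma_px_per_frame,
              exclusion_frac = exclusion_frac,
              nucleus_radius_um = nucleus_radius_um,
              cell_cycle_params = cell_cycle_params,
              reporter_kinetics = reporter_kinetics,
              hill_params = as_hill_params(hill_params),
              ndcdt1_range = ndcdt1_range,
              camera = camera, fixed = fixed,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (length(cfg$field_size_px) != 2 || any(cfg$field_size_px < 64))
    stopf("field_size_px must be a pair with each side >= 64")
  if (cfg$frame_interval_min <= 0 || cfg$n_frames < 1)
    stopf("frame timing must be positive")
  for (ph in c("g1", "s", "g2m")) {
    d <- cfg$cell_cycle_params[[ph]]
    if (is.null(d) || d[[1]] <= 0) stopf("phase '%s' duration must be > 0", ph)
  }
  if (any(cfg$nucleus_radius_um <= 0)) stopf("nucleus radius must be > 0")
  r_px <- min(cfg$nucleus_radius_um) / cfg$pixel_size_um
  if (cfg$motion_sigma_px_per_frame >= r_px)
    stopf("motion sigma (%.1f px) must be below the nucleus radius (%.1f px)",
          cfg$motion_sigma_px_per_frame, r_px)
  bt <- cfg$camera$bleedthrough
  if (length(bt) && (any(unlist(bt) < 0) || any(unlist(bt) >= 1)))
    stopf("bleedthrough coefficients must lie in [0, 1)")
  if ((cfg$camera$offset %||% 0) < 0) stopf("camera offset must be >= 0")
  if ((cfg$fixed$magnification_ratio %||% 1) < 1)
    stopf("magnification ratio must be >= 1")
  # density bound on the expected end-of-movie population
  cycle_min <- sum(vapply(cfg$cell_cycle_params, function(d) d[[1]], 0))
  movie_min <- cfg$n_frames * cfg$frame_interval_min
  n_end <- cfg$n_cells_initial * 2^(movie_min / cycle_min)
  r_mean_px <- mean(cfg$nucleus_radius_um) / cfg$pixel_size_um
  excl <- cfg$exclusion_frac %||% 0
  if (excl > 0) {
    # packing: each nucleus needs a disc of radius excl * r around it
    packing <- n_end * pi * (excl * r_mean_px)^2 / prod(cfg$field_size_px)
    if (packing > 0.55)
      stopf("expected density too high: packing fraction %.2f > 0.55", packing)
  } else {
    # free diffusion: bound the overlapping-nuclei fraction at 20%
    overlap_frac <- 1 - exp(-n_end * pi * (2 * r_mean_px)^2 /
                              prod(cfg$field_size_px))
    if (overlap_frac > 0.2)
      stopf("expected density too high: overlapping-nuclei fraction %.2f > 0.20",
            overlap_frac)
  }
  invisible(cfg)
}

# Illumination gain field (mean approximately 1) for a config.
illumination_field <- function(cfg) {
  dims <- cfg$field_size_px
  ill <- cfg$camera$illumination %||% "flat"
  if (is.matrix(ill)) {
    if (!all(dim(ill) == dims)) stopf("illumination matrix has wrong shape")
    prof <- ill
  } else if (identical(ill, "flat")) {
    prof <- matrix(1, dims[1], dims[2])
  } else if (identical(ill, "gaussian")) {
    amp <- cfg$camera$illumination_amplitude %||% 0.25
    yc <- (dims[1] - 1) / 2; xc <- (dims[2] - 1) / 2
    y <- (seq_len(dims[1]) - 1 - yc) / dims[1]
    x <- (seq_len(dims[2]) - 1 - xc) / dims[2]
    prof <- exp(-outer(y^2, rep(1, dims[2])) * 2 * amp -
                  outer(rep(1, dims[1]), x^2) * 2 * amp)
  } else stopf("unknown illumination descriptor")
  if (any(prof <= 0)) stopf("illumination profile must be strictly positive")
  prof / mean(prof)
}
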