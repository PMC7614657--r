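# Plain-file interfaces: multipage TIFF stacks, ground-truth CSV, config
# JSON. Images are written 16-bit (counts / 65535) unless float is requested.

#' Write an image stack as a multipage TIFF
#'
#' @param stack list of matrices (counts).
#' @param path output file.
#' @param max_count full-scale value for 16-bit quantization.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, max_count = 65535) {
  pages <- lapply(stack, function(m) pmin(pmax(m / max_count, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multipage TIFF written by [write_image_stack()]
#'
#' @param path TIFF file.
#' @param max_count full-scale value used at write time.
#' @return list of matrices (counts).
#' @export
read_image_stack <- function(path, max_count = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) m * max_count)
}

#' Save a simulated site to disk
#'
#' Writes one multipage TIFF per live channel, the fixed-snapshot channels,
#' the ground-truth tables as CSV, and the configuration as JSON.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param channels live channels to write.
#' @return list of written paths, invisibly.
#' @export
save_simulated_site <- function(config, out_dir,
                                channels = c("H2B", "CRL4", "APCC",
                                             "PCNAFOCI")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop <- simulate_population(config)
  mv <- render_movie(pop, config, channels)
  paths <- list()
  for (ch in channels) {
    p <- file.path(out_dir, sprintf("live_%s.tif", ch))
    write_image_stack(mv$stacks[[ch]], p)
    paths[[ch]] <- p
  }
  fx <- render_fixed_snapshot(pop, config)
  for (ch in names(fx$images)) {
    p <- file.path(out_dir, sprintf("fixed_%s.tif", ch))
    write_image_stack(list(fx$images[[ch]]), p)
    paths[[paste0("fixed_", ch)]] <- p
  }
  utils::write.csv(pop$cells, file.path(out_dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(pop$frames, file.path(out_dir, "truth_frames.csv"),
                   row.names = FALSE)
  utils::write.csv(fx$truth, file.path(out_dir, "truth_fixed.csv"),
                   row.names = FALSE)
  cfg_out <- config
  cfg_out$hill_params <- unclass(cfg_out$hill_params)
  jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Read a simulation configuration from JSON or YAML
#'
#' @param path `.json` or `.yaml`/`.yml` file with [sim_config()] fields.
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  raw$hill_params <- do.call(hill_params, as.list(raw$hill_params))
  known <- names(formals(sim_config))
  do.call(sim_config, raw[intersect(names(raw), known)])
}
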