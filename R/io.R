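#' Read and write localization tables (ThunderSTORM CSV dialect)
#'
#' Tables are CSV files with the header
#' `frame,x [nm],y [nm],uncertainty [nm],intensity [photon],channel`
#' (column order is irrelevant; parsing is header-driven). On reading,
#' rows with non-finite coordinates or non-positive uncertainty are
#' dropped with a warning reporting the count; a missing required column
#' is a hard error naming it.
#'
#' @param path CSV file path.
#' @param table localization tibble with columns `frame, x, y,
#'   uncertainty, intensity, channel`.
#' @return `read_localizations()`: a validated tibble;
#'   `write_localizations()`: the path, invisibly.
#' @export
read_localizations <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  req <- c(frame = "frame", x = "x [nm]", y = "y [nm]",
           uncertainty = "uncertainty [nm]",
           intensity = "intensity [photon]", channel = "channel")
  missing_cols <- req[!req %in% names(raw)]
  abort_if(length(missing_cols) > 0,
           paste0("missing required column(s): ",
                  paste0("'", missing_cols, "'", collapse = ", ")))
  out <- tibble::tibble(frame = as.integer(raw[[req["frame"]]]),
                        x = as.numeric(raw[[req["x"]]]),
                        y = as.numeric(raw[[req["y"]]]),
                        uncertainty = as.numeric(raw[[req["uncertainty"]]]),
                        intensity = as.numeric(raw[[req["intensity"]]]),
                        channel = as.integer(raw[[req["channel"]]]))
  bad <- !is.finite(out$x) | !is.finite(out$y) |
    !is.finite(out$uncertainty) | out$uncertainty <= 0
  if (any(bad)) {
    rlang::warn(sprintf("dropped %d invalid localization row(s)", sum(bad)))
    out <- out[!bad, ]
  }
  out
}

#' @rdname read_localizations
#' @export
write_localizations <- function(table, path) {
  df <- data.frame(frame = table$frame, x = table$x, y = table$y,
                   uncertainty = table$uncertainty,
                   intensity = table$intensity, channel = table$channel,
                   check.names = FALSE)
  names(df) <- c("frame", "x [nm]", "y [nm]", "uncertainty [nm]",
                 "intensity [photon]", "channel")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write images as TIFF with a JSON metadata sidecar
#'
#' Images are written as 32-bit float TIFF (multi-channel images as one
#' page per channel) with the pixel size recorded in a JSON sidecar
#' `<path>.meta.json`. On reading, an explicit `pixel_size_nm` override
#' wins over the sidecar; if both are missing, reading fails.
#'
#' @param image matrix or named list of matrices (channels).
#' @param path TIFF path.
#' @param pixel_size_nm pixel size (nm).
#' @return `read_image()`: list with `channels` (list of matrices) and
#'   `pixel_size_nm`; `write_image()`: the path, invisibly.
#' @export
write_image <- function(image, path, pixel_size_nm) {
  assert_positive(pixel_size_nm, "pixel_size_nm")
  chans <- if (is.matrix(image)) list(image) else image
  # TIFF samples are stored in [0, 1]; record the affine intensity scaling
  # per channel in the sidecar and undo it on read
  offsets <- purrr::map_dbl(chans, min)
  scales <- purrr::map_dbl(chans, ~ max(max(.x) - min(.x), 1e-300))
  stored <- purrr::map(seq_along(chans), function(k) {
    m <- (chans[[k]] - offsets[k]) / scales[k]
    matrix(pmin(pmax(as.numeric(m), 0), 1), nrow(chans[[k]]))
  })
  tiff::writeTIFF(stored, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_nm = pixel_size_nm, n_channels = length(chans),
         channel_names = names(chans),
         intensity_offset = unname(offsets), intensity_scale = unname(scales)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, pixel_size_nm = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  ps <- pixel_size_nm %||% meta$pixel_size_nm
  abort_if(is.null(ps),
           "pixel size missing from both the metadata sidecar and the override")
  chans <- purrr::map(seq_along(pages), function(k) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    m <- matrix(as.numeric(pg), nrow(pg))
    if (!is.null(meta$intensity_scale)) {
      m <- m * meta$intensity_scale[[k]] + meta$intensity_offset[[k]]
    }
    m
  })
  if (!is.null(meta$channel_names) && length(meta$channel_names) == length(chans)) {
    names(chans) <- unlist(meta$channel_names)
  }
  list(channels = chans, pixel_size_nm = as.numeric(ps))
}

#' Read and write AFM force curves as CSV
#'
#' Columns: `time [s],force [nN],z [um]`.
#'
#' @param curve tibble `time_s`, `force_nN`, `z_um`.
#' @param path CSV path.
#' @export
write_force_curve <- function(curve, path) {
  df <- data.frame(curve$time_s, curve$force_nN, curve$z_um)
  names(df) <- c("time [s]", "force [nN]", "z [um]")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  req <- c("time [s]", "force [nN]", "z [um]")
  missing_cols <- req[!req %in% names(raw)]
  abort_if(length(missing_cols) > 0,
           paste0("missing required column(s): ",
                  paste0("'", missing_cols, "'", collapse = ", ")))
  tibble::tibble(time_s = raw[["time [s]"]], force_nN = raw[["force [nN]"]],
                 z_um = raw[["z [um]"]])
}

#' Pipeline configuration
#'
#' Central container for the tunable lengths and thresholds of the
#' pipeline, with the field defaults: 10 nm rendering pixels so that the
#' 200 nm cortex bins span 20 pixels, 200-400 nm head pairing, 50 nm
#' tail validation, 170 nm confocal PSF sigma.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    render_pixel_nm = 10,
    bin_width_nm = 200,
    bin_width_px = 20,
    half_width_nm = 500,
    pair_d_min_nm = 200,
    pair_d_max_nm = 400,
    tail_radius_nm = 50,
    rcc_window_frames = 2000,
    rcc_subpixel_nm = 20,
    rollingball_radius_px = 50,
    band_px = 8,
    confocal_psf_sigma_nm = 170,
    minifil_l_ref_nm = 317)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  abort_if(length(bad) > 0,
           paste("unknown config field(s):", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  lens <- unlist(cfg[grepl("_nm$|_px$|_frames$", names(cfg))])
  abort_if(any(lens <= 0), "all lengths and window sizes must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a JSON run manifest
#'
#' Records the configuration, the seeds, package and R versions, and the
#' produced files, so that a run is reproducible from its manifest alone.
#'
#' @param path JSON path.
#' @param config a [pipeline_config()].
#' @param seeds named list/vector of the seeds used.
#' @param files character vector of produced files.
#' @export
write_run_manifest <- function(path, config, seeds, files = character()) {
  jsonlite::write_json(
    list(package = "cortexmap",
         version = as.character(utils::packageVersion("cortexmap")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC"),
         config = unclass(config),
         seeds = as.list(seeds),
         files = files),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
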