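#' Synthetic two-colour SMLM scene of an equatorial cell cortex
#'
#' Describes a circular cell imaged at its midplane: an actin band hugging
#' the membrane plus a second channel (myosin, alpha-actinin, moesin, or a
#' second actin label) at a configurable depth, with per-localization
#' uncertainty, stage drift, chromatic distortion and fiducial beads.
#'
#' Band offsets are depths below the membrane measured along the transverse
#' axis that points into the cytoplasm (positive = deeper inside the cell).
#' Radial positions of molecules are Gaussian about `cell_radius - offset`
#' with the stated FWHM; angular positions are uniform. The localization
#' uncertainty is drawn from a truncated normal with mean 20 nm and SD
#' 10 nm, matching typical dSTORM performance.
#'
#' @param cell_center length-2, cell centre in nm.
#' @param cell_radius cell radius in nm.
#' @param actin_band,target_band lists with elements `offset_nm` (depth of
#'   the band centre below the membrane), `fwhm_nm`, and `n` localizations.
#' @param uncertainty_mean_nm,uncertainty_sd_nm localization-uncertainty
#'   model (truncated at > 2 nm).
#' @param n_frames number of acquisition frames.
#' @param drift_fn `NULL` for no drift, or a function of a frame-index
#'   vector returning an n x 2 matrix of absolute drift (nm) per frame;
#'   see [linear_drift()] and [sinusoidal_drift()].
#' @param chromatic_affine [affine2d()] applied to the target channel.
#' @param beads k x 2 matrix of fiducial bead positions (nm); beads emit
#'   one localization per frame in both channels.
#' @param bead_jitter_nm SD of the bead localization scatter.
#' @return An object of class `cortex_scene`.
#' @export
cortex_scene <- function(cell_center = c(4000, 4000),
                         cell_radius = 2500,
                         actin_band = list(offset_nm = 100, fwhm_nm = 200, n = 20000),
                         target_band = list(offset_nm = 140, fwhm_nm = 220, n = 20000),
                         uncertainty_mean_nm = 20,
                         uncertainty_sd_nm = 10,
                         n_frames = 20000,
                         drift_fn = NULL,
                         chromatic_affine = identity_affine(),
                         beads = NULL,
                         bead_jitter_nm = 3) {
  assert_positive(cell_radius, "cell_radius")
  for (b in list(actin_band, target_band)) {
    assert_positive(b$fwhm_nm, "band fwhm_nm")
    assert_positive(b$n, "band localization count")
  }
  assert_positive(uncertainty_mean_nm, "uncertainty_mean_nm")
  assert_positive(n_frames, "n_frames")
  structure(list(cell_center = cell_center, cell_radius = cell_radius,
                 actin_band = actin_band, target_band = target_band,
                 uncertainty_mean_nm = uncertainty_mean_nm,
                 uncertainty_sd_nm = uncertainty_sd_nm,
                 n_frames = as.integer(n_frames), drift_fn = drift_fn,
                 chromatic_affine = chromatic_affine, beads = beads,
                 bead_jitter_nm = bead_jitter_nm),
            class = "cortex_scene")
}

#' Drift trajectories for synthetic acquisitions
#'
#' @param total_nm length-2, total displacement accumulated linearly over
#'   the acquisition.
#' @param amplitude_nm,period_frames sinusoid parameters (x only).
#' @return A function mapping a frame vector to an n x 2 drift matrix (nm).
#' @export
linear_drift <- function(total_nm = c(100, 0)) {
  force(total_nm)
  function(frames, n_frames) {
    f <- (frames - 1) / max(n_frames - 1, 1)
    cbind(f * total_nm[1], f * total_nm[2])
  }
}

#' @rdname linear_drift
#' @export
sinusoidal_drift <- function(amplitude_nm = 50, period_frames = 10000) {
  force(amplitude_nm); force(period_frames)
  function(frames, n_frames) {
    cbind(amplitude_nm * sin(2 * pi * (frames - 1) / period_frames),
          rep(0, length(frames)))
  }
}

rtruncnorm_pos <- function(n, mean, sd, lower = 2) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

band_interval <- function(band) {
  c(band$offset_nm - band$fwhm_nm / 2, band$offset_nm + band$fwhm_nm / 2)
}

#' Generate a two-colour SMLM localization dataset of a cell cortex
#'
#' Draws localizations on the annular bands of a [cortex_scene()], injects
#' cumulative drift, applies the chromatic affine to the target channel
#' only, adds always-on fiducial beads to both channels, and records the
#' ground truth, including the analytically implied cytoplasmic overhang
#' of the target band relative to the actin band (interval arithmetic on
#' the two FWHM intervals along the inward transverse axis).
#'
#' @param spec A [cortex_scene()].
#' @param seed Integer seed; generation is fully deterministic given
#'   `spec` and `seed`.
#' @return List with localization tibbles `actin` and `target` (columns
#'   `frame, x, y, uncertainty, intensity, channel`) and a `truth` list
#'   (band geometry, drift trajectory, affine, true overhang and
#'   peak-to-peak distance).
#' @export
gen_smlm_cortex <- function(spec, seed) {
  stopifnot(inherits(spec, "cortex_scene"))
  set.seed(seed)
  frames_all <- seq_len(spec$n_frames)
  drift <- if (is.null(spec$drift_fn)) {
    matrix(0, spec$n_frames, 2)
  } else {
    m <- spec$drift_fn(frames_all, spec$n_frames)
    stopifnot(nrow(m) == spec$n_frames)
    m
  }

  draw_band <- function(band, channel, distort) {
    n <- band$n
    phi <- stats::runif(n, 0, 2 * pi)
    depth <- stats::rnorm(n, band$offset_nm, band$fwhm_nm / FWHM_PER_SIGMA)
    r <- spec$cell_radius - depth
    x <- spec$cell_center[1] + r * cos(phi)
    y <- spec$cell_center[2] + r * sin(phi)
    unc <- rtruncnorm_pos(n, spec$uncertainty_mean_nm, spec$uncertainty_sd_nm)
    x <- x + stats::rnorm(n, 0, unc)
    y <- y + stats::rnorm(n, 0, unc)
    frame <- sample.int(spec$n_frames, n, replace = TRUE)
    x <- x + drift[frame, 1]
    y <- y + drift[frame, 2]
    if (distort) {
      xy <- apply_affine(cbind(x, y), spec$chromatic_affine)
      x <- xy[, 1]; y <- xy[, 2]
    }
    tibble::tibble(frame = frame, x = x, y = y, uncertainty = unc,
                   intensity = stats::rpois(n, 1000), channel = channel)
  }

  draw_beads <- function(channel, distort) {
    if (is.null(spec$beads)) return(NULL)
    beads <- as.matrix(spec$beads)
    purrr::map_dfr(seq_len(nrow(beads)), function(k) {
      x <- beads[k, 1] + drift[, 1] +
        stats::rnorm(spec$n_frames, 0, spec$bead_jitter_nm)
      y <- beads[k, 2] + drift[, 2] +
        stats::rnorm(spec$n_frames, 0, spec$bead_jitter_nm)
      if (distort) {
        xy <- apply_affine(cbind(x, y), spec$chromatic_affine)
        x <- xy[, 1]; y <- xy[, 2]
      }
      tibble::tibble(frame = frames_all, x = x, y = y,
                     uncertainty = spec$bead_jitter_nm,
                     intensity = stats::rpois(spec$n_frames, 5000),
                     channel = channel)
    })
  }

  actin <- dplyr::bind_rows(draw_band(spec$actin_band, 1L, FALSE),
                            draw_beads(1L, FALSE))
  target <- dplyr::bind_rows(draw_band(spec$target_band, 2L, TRUE),
                             draw_beads(2L, TRUE))

  a_int <- band_interval(spec$actin_band)
  t_int <- band_interval(spec$target_band)
  truth <- list(
    cell_center = spec$cell_center,
    cell_radius = spec$cell_radius,
    actin_interval_nm = a_int,
    target_interval_nm = t_int,
    true_overhang_pct = overhang_interval(a_int[1], a_int[2],
                                          t_int[1], t_int[2]),
    true_peak_to_peak_nm = spec$target_band$offset_nm - spec$actin_band$offset_nm,
    drift_nm = drift,
    chromatic_affine = spec$chromatic_affine,
    beads = spec$beads
  )
  list(actin = actin, target = target, truth = truth)
}
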