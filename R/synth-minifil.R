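#' Synthetic two-channel SIM scene of bipolar myosin minifilaments
#'
#' A nonmuscle myosin II minifilament appears in two-colour SIM as two
#' head spots (green channel) flanking one tail spot (red channel) at
#' their midpoint. Each synthetic filament has a true 3D length and an
#' out-of-plane angle theta; its in-plane projected head separation is
#' `true_length * cos(theta)`. Spots are Gaussian with the SIM point
#' spread, added over a smooth inhomogeneous background, with Poisson
#' photon noise plus Gaussian read noise.
#'
#' The orientation distribution is uniform in theta over
#' `[0, theta_max_deg]` by default: the cortex confines minifilaments to
#' shallow out-of-plane angles, and the flat-in-theta choice is a
#' configurable convention rather than an assertion about the real
#' distribution.
#'
#' @param n_filaments number of filaments.
#' @param true_length_nm true head-to-head length (default 317 nm, the
#'   stress-fiber reference; 330 nm is the electron-microscopy
#'   alternative).
#' @param theta_max_deg upper limit of the uniform out-of-plane angle.
#' @param image_size_px image side (square image).
#' @param pixel_size_nm SIM pixel size.
#' @param psf_sigma_nm Gaussian PSF sigma of the reconstructed SIM image.
#' @param head_photons,tail_photons expected photons per spot.
#' @param background list: `offset` (counts), `amplitude` and `scale_px`
#'   of a smooth random background field.
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param margin_nm exclusion margin so that no filament touches the
#'   image border region.
#' @return An object of class `minifil_scene`.
#' @export
minifil_scene <- function(n_filaments = 30,
                          true_length_nm = 317,
                          theta_max_deg = 30,
                          image_size_px = 256,
                          pixel_size_nm = 40,
                          psf_sigma_nm = 60,
                          head_photons = 2000,
                          tail_photons = 1500,
                          background = list(offset = 10, amplitude = 5,
                                            scale_px = 300),
                          read_noise_sd = 2,
                          margin_nm = 500) {
  abort_if(true_length_nm < 200 || true_length_nm > 400,
           "true_length_nm must lie in [200, 400] nm")
  assert_positive(pixel_size_nm, "pixel_size_nm")
  assert_positive(psf_sigma_nm, "psf_sigma_nm")
  assert_positive(n_filaments, "n_filaments")
  structure(as.list(environment()), class = "minifil_scene")
}

#' Render isotropic Gaussian spots on a pixel grid
#'
#' Utility for building synthetic fluorescence images: each spot deposits
#' `photons` total counts as a Gaussian of the given PSF sigma.
#'
#' @param xy_nm n x 2 matrix of spot positions (nm).
#' @param photons vector of expected counts per spot.
#' @param size_px image side (square).
#' @param pixel_nm pixel size.
#' @param sigma_nm PSF sigma.
#' @return image matrix (counts).
#' @export
render_spots <- function(xy_nm, photons, size_px, pixel_nm, sigma_nm) {
  img <- matrix(0, size_px, size_px)
  if (length(photons) == 0) return(img)
  half <- ceiling(4 * sigma_nm / pixel_nm)
  for (i in seq_len(nrow(xy_nm))) {
    jc <- xy_nm[i, 1] / pixel_nm + 0.5
    ic <- xy_nm[i, 2] / pixel_nm + 0.5
    jr <- max(1, floor(jc - half)):min(size_px, ceiling(jc + half))
    ir <- max(1, floor(ic - half)):min(size_px, ceiling(ic + half))
    gx <- stats::dnorm((jr - 0.5) * pixel_nm, xy_nm[i, 1], sigma_nm) * pixel_nm
    gy <- stats::dnorm((ir - 0.5) * pixel_nm, xy_nm[i, 2], sigma_nm) * pixel_nm
    img[ir, jr] <- img[ir, jr] + photons[i] * outer(gy, gx)
  }
  img
}

#' Generate a synthetic two-channel minifilament image
#'
#' @param spec a [minifil_scene()].
#' @param seed integer seed (generation is deterministic given both).
#' @return list: `green` and `red` image matrices (counts), `pixel_size_nm`,
#'   and `truth` tibble (`x_nm`, `y_nm`, in-plane direction `phi_deg`,
#'   out-of-plane `theta_deg`, `projected_length_nm`, `detectable`). A
#'   filament whose projection collapses (heads within one PSF sigma) is
#'   marked undetectable. Scenes denser than one filament per
#'   (2 x true length)^2 trigger a pairing-ambiguity warning.
#' @export
gen_sim_minifilaments <- function(spec, seed) {
  stopifnot(inherits(spec, "minifil_scene"))
  set.seed(seed)
  n <- spec$n_filaments
  side_nm <- spec$image_size_px * spec$pixel_size_nm
  area_um2 <- (side_nm / 1000)^2
  if (n / area_um2 > 1 / (2 * spec$true_length_nm / 1000)^2) {
    rlang::warn("filament density exceeds 1 per (2 L)^2; head pairing may be ambiguous")
  }
  m <- spec$margin_nm
  cx <- stats::runif(n, m, side_nm - m)
  cy <- stats::runif(n, m, side_nm - m)
  theta <- stats::runif(n, 0, spec$theta_max_deg) * pi / 180
  phi <- stats::runif(n, 0, 2 * pi)
  proj <- spec$true_length_nm * cos(theta)
  hx <- proj / 2 * cos(phi); hy <- proj / 2 * sin(phi)
  heads <- rbind(cbind(cx + hx, cy + hy), cbind(cx - hx, cy - hy))
  tails <- cbind(cx, cy)
  green <- render_spots(heads, stats::rpois(2 * n, spec$head_photons),
                        spec$image_size_px, spec$pixel_size_nm,
                        spec$psf_sigma_nm)
  red <- render_spots(tails, stats::rpois(n, spec$tail_photons),
                      spec$image_size_px, spec$pixel_size_nm,
                      spec$psf_sigma_nm)
  bg <- spec$background
  field <- gaussian_blur(matrix(stats::rnorm(spec$image_size_px^2),
                                spec$image_size_px),
                         bg$scale_px)
  field <- bg$offset + bg$amplitude * field / max(stats::sd(field), 1e-12)
  noisy <- function(img) {
    out <- stats::rpois(length(img), pmax(img + field, 0)) +
      stats::rnorm(length(img), 0, spec$read_noise_sd)
    matrix(out, nrow(img))
  }
  truth <- tibble::tibble(
    x_nm = cx, y_nm = cy,
    phi_deg = phi * 180 / pi,
    theta_deg = theta * 180 / pi,
    projected_length_nm = proj,
    detectable = proj > spec$psf_sigma_nm)
  list(green = noisy(green), red = noisy(red),
       pixel_size_nm = spec$pixel_size_nm, truth = truth)
}
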