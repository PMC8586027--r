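#' Forward model: piecewise-constant cortex density blurred by the PSF
#'
#' The fluorophore density across the cell boundary is modelled as steps:
#' an extracellular level `i_out` before the membrane at `x_m`, a
#' cortical level `i_cort` over `[x_m, x_m + h]`, and a cytoplasmic level
#' `i_in` beyond; the observed linescan is this profile convolved with a
#' Gaussian PSF of standard deviation `sigma`. The same closed form
#' (erf-based) is used by the generator and the fitter, so a noiseless
#' generated linescan is reproduced exactly by the fit model.
#'
#' @param x positions (nm).
#' @param x_m membrane position (nm).
#' @param h slab thickness (nm).
#' @param i_out,i_cort,i_in density levels (a.u.).
#' @param sigma PSF sigma (nm); `sigma = 0` gives the unblurred steps.
#' @return intensity at `x`.
#' @export
step_convolution_model <- function(x, x_m, h, i_out, i_cort, i_in, sigma) {
  edge <- function(x0) if (sigma > 0) stats::pnorm((x - x0) / sigma) else as.numeric(x >= x0)
  i_out + (i_cort - i_out) * edge(x_m) + (i_in - i_cort) * edge(x_m + h)
}

#' Forward model for the myosin layer pinned at the cortex inner edge
#'
#' Myosin occupies a slab of width `h_myo` whose cytoplasmic edge
#' coincides with the cytoplasmic edge of the actin cortex at
#' `inner_edge = x_m + h_actin`; the slab extends from there toward the
#' membrane. Levels: `m_bg` on the membrane side of the slab (covering
#' the extracellular space and any myosin-free cortex gap), `m_cort`
#' within the slab, `m_in` in the cytoplasm.
#'
#' @param x positions (nm).
#' @param inner_edge cytoplasmic edge of the actin cortex (nm).
#' @param h_myo myosin slab width (nm).
#' @param m_bg,m_cort,m_in density levels.
#' @param sigma PSF sigma (nm).
#' @export
myosin_step_model <- function(x, inner_edge, h_myo, m_bg, m_cort, m_in, sigma) {
  step_convolution_model(x, inner_edge - h_myo, h_myo, m_bg, m_cort, m_in,
                         sigma)
}

#' Synthetic confocal linescan specification
#'
#' @param x_m membrane position (nm).
#' @param h_actin actin cortex thickness (nm).
#' @param h_myo myosin penetration depth (nm); must satisfy
#'   `0 < h_myo <= h_actin` in the aligned-edge model.
#' @param i_out,i_cort,i_in actin density levels (a.u.).
#' @param m_bg,m_cort,m_in myosin density levels (a.u.).
#' @param psf_sigma_nm confocal PSF sigma (default 170 nm).
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param range_nm scan range, `c(lo, hi)` about the membrane.
#' @param step_nm sampling step.
#' @return object of class `linescan_scene`.
#' @export
linescan_scene <- function(x_m = 1000, h_actin = 230, h_myo = 150,
                           i_out = 5, i_cort = 100, i_in = 30,
                           m_bg = 5, m_cort = 80, m_in = 20,
                           psf_sigma_nm = 170, noise_sd = 0,
                           range_nm = c(-2000, 3000), step_nm = 20) {
  assert_positive(h_actin, "h_actin")
  abort_if(h_myo <= 0 || h_myo > h_actin,
           "h_myo must satisfy 0 < h_myo <= h_actin")
  abort_if(psf_sigma_nm < 0, "psf_sigma_nm must be >= 0")
  structure(as.list(environment()), class = "linescan_scene")
}

#' Generate a two-channel synthetic linescan
#'
#' @param spec a [linescan_scene()].
#' @param seed integer seed.
#' @return tibble `distance_nm`, `actin`, `myosin` with attribute `truth`
#'   (the spec plus the implied myosin-free cortex length
#'   `h_actin - h_myo`).
#' @export
gen_linescan <- function(spec, seed) {
  stopifnot(inherits(spec, "linescan_scene"))
  set.seed(seed)
  x <- seq(spec$x_m + spec$range_nm[1], spec$x_m + spec$range_nm[2],
           by = spec$step_nm)
  actin <- step_convolution_model(x, spec$x_m, spec$h_actin, spec$i_out,
                                  spec$i_cort, spec$i_in, spec$psf_sigma_nm)
  myo <- myosin_step_model(x, spec$x_m + spec$h_actin, spec$h_myo,
                           spec$m_bg, spec$m_cort, spec$m_in,
                           spec$psf_sigma_nm)
  if (spec$noise_sd > 0) {
    actin <- actin + stats::rnorm(length(x), 0, spec$noise_sd)
    myo <- myo + stats::rnorm(length(x), 0, spec$noise_sd)
  }
  out <- tibble::tibble(distance_nm = x, actin = actin, myosin = myo)
  attr(out, "truth") <- c(unclass(spec),
                          list(myosin_free_length_nm = spec$h_actin - spec$h_myo))
  out
}
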