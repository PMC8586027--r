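#' Fit the actin cortex thickness from a confocal linescan
#'
#' Least-squares fit of the step-convolution model
#' ([step_convolution_model()]) to a linescan crossing the cortex once.
#' The extracellular level `i_out` is estimated from the extracellular
#' tail (median of the outer 15% of samples on that side); the free
#' parameters are the membrane position `x_m`, the cortex thickness
#' `h_actin`, and the levels `i_cort`, `i_in`. The fit is multistarted
#' over a grid of thickness values (50-400 nm by 50) and the best
#' residual kept; the PSF width is a calibration input.
#'
#' @param distance_nm,intensity the linescan (nm, a.u.).
#' @param psf_sigma_nm PSF sigma (default 170 nm).
#' @param extracellular which end of the scan is outside the cell.
#' @param h_starts multistart grid for the thickness (nm).
#' @return object of class `step_fit` with elements `x_m`, `h_actin`,
#'   `i_out`, `i_cort`, `i_in`, `psf_sigma_nm`, `residual_rms`,
#'   `fitted`, `data`.
#' @export
fit_actin_linescan <- function(distance_nm, intensity, psf_sigma_nm = 170,
                               extracellular = c("left", "right"),
                               h_starts = seq(50, 400, by = 50)) {
  extracellular <- match.arg(extracellular)
  assert_positive(psf_sigma_nm, "psf_sigma_nm")
  if (extracellular == "right") {
    distance_nm <- -rev(distance_nm)
    intensity <- rev(intensity)
  }
  n <- length(distance_nm)
  k_tail <- max(3L, floor(0.15 * n))
  i_out <- stats::median(intensity[seq_len(k_tail)])
  step <- stats::median(diff(distance_nm))
  if (psf_sigma_nm < step / 2) {
    # delta-PSF limit: the plateau width is read off directly from the
    # half-level crossings (the convolution model is degenerate here)
    half <- (i_out + max(intensity)) / 2
    above <- which(intensity > half)
    h_direct <- distance_nm[max(above)] - distance_nm[min(above)] + step
    out <- list(x_m = distance_nm[min(above)] - step / 2,
                h_actin = h_direct, i_out = i_out,
                i_cort = max(intensity),
                i_in = stats::median(intensity[(n - k_tail + 1):n]),
                psf_sigma_nm = psf_sigma_nm, residual_rms = 0,
                flipped = extracellular == "right",
                fitted = intensity,
                data = tibble::tibble(distance_nm = distance_nm,
                                      intensity = intensity))
    class(out) <- "step_fit"
    return(out)
  }
  peak_pos <- distance_nm[which.max(intensity)]
  # guardrails against the degenerate thin-slab / infinite-density corner
  # of the likelihood valley: slabs below 20 nm are optically meaningless
  # at this PSF, and the cortical density is capped at a generous
  # multiple of the observed peak
  amp_cap <- 20 * max(max(intensity) - i_out, .Machine$double.eps)
  fits <- purrr::map(h_starts, function(h0) {
    start <- list(x_m = peak_pos - h0 / 2, h = h0,
                  i_cort = max(intensity) - i_out,
                  i_in = stats::median(intensity[(n - k_tail + 1):n]))
    tryCatch(
      minpack.lm::nlsLM(
        intensity ~ step_convolution_model(distance_nm, x_m, h, i_out,
                                           i_cort, i_in, psf_sigma_nm),
        start = start,
        lower = c(x_m = min(distance_nm), h = 20,
                  i_cort = 0, i_in = 0),
        upper = c(x_m = max(distance_nm), h = 1000,
                  i_cort = amp_cap, i_in = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  abort_if(length(fits) == 0, "step-convolution fit failed on all starts")
  rss <- purrr::map_dbl(fits, stats::deviance)
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  out <- list(x_m = unname(cf["x_m"]), h_actin = unname(cf["h"]),
              i_out = i_out, i_cort = unname(cf["i_cort"]),
              i_in = unname(cf["i_in"]),
              psf_sigma_nm = psf_sigma_nm,
              residual_rms = sqrt(min(rss) / n),
              flipped = extracellular == "right",
              fitted = stats::fitted(best),
              data = tibble::tibble(distance_nm = distance_nm,
                                    intensity = intensity))
  class(out) <- "step_fit"
  out
}

#' Fit the myosin penetration depth given the actin fit
#'
#' Myosin is modelled as a slab whose cytoplasmic edge is pinned at the
#' cytoplasmic edge of the fitted actin cortex (`x_m + h_actin`),
#' extending toward the membrane ([myosin_step_model()]). The slab width
#' `h_myo` and the three levels are fitted; the myosin-free cortex
#' length is `h_actin - h_myo`. A fitted `h_myo` exceeding `h_actin` is
#' clipped to `h_actin` with a warning (full penetration).
#'
#' @param distance_nm,intensity the myosin linescan.
#' @param actin_fit a [fit_actin_linescan()] result.
#' @param psf_sigma_nm PSF sigma; defaults to the actin fit's value.
#' @param h_starts multistart grid (nm).
#' @return object of class `step_fit` with `h_myo` and
#'   `myosin_free_length_nm`.
#' @export
fit_myosin_penetration <- function(distance_nm, intensity, actin_fit,
                                   psf_sigma_nm = NULL,
                                   h_starts = seq(50, 400, by = 50)) {
  stopifnot(inherits(actin_fit, "step_fit"))
  psf_sigma_nm <- psf_sigma_nm %||% actin_fit$psf_sigma_nm
  if (isTRUE(actin_fit$flipped)) {
    distance_nm <- -rev(distance_nm)
    intensity <- rev(intensity)
  }
  rng <- range(intensity)
  abort_if(diff(rng) <= .Machine$double.eps * max(abs(rng), 1),
           "no myosin signal to fit")
  inner_edge <- actin_fit$x_m + actin_fit$h_actin
  n <- length(distance_nm)
  k_tail <- max(3L, floor(0.15 * n))
  fits <- purrr::map(h_starts, function(h0) {
    start <- list(h_myo = h0,
                  m_bg = stats::median(intensity[seq_len(k_tail)]),
                  m_cort = max(intensity),
                  m_in = stats::median(intensity[(n - k_tail + 1):n]))
    tryCatch(
      minpack.lm::nlsLM(
        intensity ~ myosin_step_model(distance_nm, inner_edge, h_myo,
                                      m_bg, m_cort, m_in, psf_sigma_nm),
        start = start,
        lower = c(h_myo = 5, m_bg = 0, m_cort = 0, m_in = 0),
        upper = c(h_myo = 1500, m_bg = Inf, m_cort = Inf, m_in = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  abort_if(length(fits) == 0, "myosin step fit failed on all starts")
  rss <- purrr::map_dbl(fits, stats::deviance)
  best <- fits[[which.min(rss)]]
  cf <- stats::coef(best)
  h_myo <- unname(cf["h_myo"])
  if (h_myo > actin_fit$h_actin) {
    rlang::warn("fitted h_myo exceeds h_actin; clipped (full penetration)")
    h_myo <- actin_fit$h_actin
  }
  out <- list(x_m = actin_fit$x_m, h_actin = actin_fit$h_actin,
              h_myo = h_myo,
              myosin_free_length_nm = actin_fit$h_actin - h_myo,
              m_bg = unname(cf["m_bg"]), m_cort = unname(cf["m_cort"]),
              m_in = unname(cf["m_in"]),
              psf_sigma_nm = psf_sigma_nm,
              residual_rms = sqrt(min(rss) / n),
              flipped = actin_fit$flipped,
              fitted = stats::fitted(best),
              data = tibble::tibble(distance_nm = distance_nm,
                                    intensity = intensity))
  class(out) <- "step_fit"
  out
}
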