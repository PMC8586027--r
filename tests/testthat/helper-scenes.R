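# Shared fixtures, built in code.

# small two-colour cortex scene (fast enough for unit tests)
small_cortex_scene <- function(target_offset = 140, target_fwhm = 220,
                               n = 20000, ...) {
  cortex_scene(cell_center = c(4000, 4000), cell_radius = 2500,
               actin_band = list(offset_nm = 100, fwhm_nm = 200, n = n),
               target_band = list(offset_nm = target_offset,
                                  fwhm_nm = target_fwhm, n = n),
               n_frames = 1000, ...)
}

render_scene <- function(gen, pixel = 10, extent = c(0, 8000, 0, 8000)) {
  list(actin = render_localizations(gen$actin, pixel, extent),
       target = render_localizations(gen$target, pixel, extent))
}

default_seed_poly <- function() circle_seed(c(4000, 4000), 2500, 72)

# 1 nm rasterized oracle for the signed cytoplasmic overhang: the part of
# the target FWHM interval protruding beyond the actin cytoplasmic edge
# counts positive, the gap between a retracted target edge and the actin
# edge counts negative; both measured by rasterizing the axis at 1 nm.
raster_overhang_oracle <- function(a_lo, a_hi, t_lo, t_hi, step = 1) {
  lo <- min(a_lo, t_lo) - 2 * step
  hi <- max(a_hi, t_hi) + 2 * step
  xs <- seq(lo + step / 2, hi, by = step)
  protrude <- sum(xs >= t_lo & xs <= t_hi & xs > a_hi) * step
  retract <- sum(xs > t_hi & xs <= a_hi) * step
  100 * (protrude - retract) / (t_hi - t_lo)
}

# cell-free border frame of a square image, as a background-noise ROI
border_roi <- function(n, w = 45) {
  m <- matrix(FALSE, n, n)
  m[1:w, ] <- TRUE; m[(n - w + 1):n, ] <- TRUE
  m[, 1:w] <- TRUE; m[, (n - w + 1):n] <- TRUE
  m
}

# straight horizontal localization band for rendering/straightening tests
straight_band_table <- function(n = 40000, y_center = 1000, fwhm = 200,
                                x_range = c(0, 6000), uncertainty = 20,
                                seed = 1) {
  set.seed(seed)
  tibble::tibble(
    frame = sample.int(100, n, replace = TRUE),
    x = stats::runif(n, x_range[1], x_range[2]),
    y = stats::rnorm(n, y_center, fwhm / (2 * sqrt(2 * log(2)))),
    uncertainty = rep(uncertainty, n),
    intensity = rep(1000, n),
    channel = 1L)
}

# exhaustive Mann-Whitney two-tailed p by permutation enumeration
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  combs <- utils::combn(length(pooled), n_a)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(a, b)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n_a * (length(pooled) - n_a) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
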