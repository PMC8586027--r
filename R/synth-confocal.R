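#' Synthetic confocal field of ring-shaped (cortical) cells
#'
#' Each cell is a bright cortical ring (annulus of the given band width
#' at the cell radius) with a dimmer interior, over a smooth
#' inhomogeneous background plus offset and Gaussian noise. Ground truth
#' stores per-cell masks and the mean cortical intensity.
#'
#' @param cells tibble/data frame with columns `x_px`, `y_px`,
#'   `radius_px`, `intensity`, `band_px` (one row per cell); cells must
#'   not overlap.
#' @param image_size_px image side.
#' @param interior_frac interior intensity as a fraction of the ring.
#' @param background list `offset`, `amplitude`, `scale_px`.
#' @param noise_sd Gaussian noise SD.
#' @return object of class `confocal_scene`.
#' @export
confocal_scene <- function(cells = tibble::tibble(x_px = 64, y_px = 64,
                                                  radius_px = 30,
                                                  intensity = 10,
                                                  band_px = 8),
                           image_size_px = 128,
                           interior_frac = 0.25,
                           background = list(offset = 1, amplitude = 0.3,
                                             scale_px = 30),
                           noise_sd = 0.1) {
  cells <- tibble::as_tibble(cells)
  if (nrow(cells) > 1) {
    d <- as.matrix(stats::dist(cells[, c("x_px", "y_px")]))
    rsum <- outer(cells$radius_px + cells$band_px, cells$radius_px + cells$band_px, "+")
    diag(d) <- Inf
    abort_if(any(d < rsum), "cells overlap")
  }
  structure(list(cells = cells, image_size_px = image_size_px,
                 interior_frac = interior_frac, background = background,
                 noise_sd = noise_sd),
            class = "confocal_scene")
}

#' Generate a synthetic confocal cell image with ground truth
#'
#' @param spec a [confocal_scene()].
#' @param seed integer seed.
#' @return list: `image` matrix, `truth` list with per-cell logical
#'   `masks` (filled cell disks) and `mean_cortical_intensity`.
#' @export
gen_confocal_cells <- function(spec, seed) {
  stopifnot(inherits(spec, "confocal_scene"))
  set.seed(seed)
  n <- spec$image_size_px
  img <- matrix(0, n, n)
  xg <- matrix(rep(seq_len(n), each = n), n)   # column index
  yg <- matrix(rep(seq_len(n), times = n), n)  # row index
  masks <- list()
  for (k in seq_len(nrow(spec$cells))) {
    cl <- spec$cells[k, ]
    r <- sqrt((xg - cl$x_px)^2 + (yg - cl$y_px)^2)
    ring <- abs(r - cl$radius_px) <= cl$band_px / 2
    interior <- r < cl$radius_px - cl$band_px / 2
    img[ring] <- img[ring] + cl$intensity
    img[interior] <- img[interior] + cl$intensity * spec$interior_frac
    masks[[k]] <- r <= cl$radius_px + cl$band_px / 2
  }
  bg <- spec$background
  if (bg$amplitude > 0) {
    field <- gaussian_blur(matrix(stats::rnorm(n * n), n), bg$scale_px)
    field <- bg$amplitude * field / max(stats::sd(field), 1e-12)
  } else field <- 0
  img <- img + bg$offset + field
  if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n)
  list(image = img,
       truth = list(masks = masks,
                    mean_cortical_intensity = spec$cells$intensity))
}
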