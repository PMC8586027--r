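#' Minifilament detection and geometry in two-channel SIM images
#'
#' Heads (green channel) and tails (red channel) are detected as local
#' maxima after background homogenization, Richardson-Lucy deconvolution
#' and noise thresholding; all green pairs separated by 200-400 nm are
#' minifilament candidates, validated by a red (tail) peak within 50 nm
#' of the pair midpoint. Projected-length statistics then translate into
#' orientation angles and a relative-tension factor under the
#' equal-contribution cosine model.
#'
#' @name minifil
NULL

#' Remove large-scale background inhomogeneity
#'
#' Subtracts a very-large-radius Gaussian blur of the image (default
#' 500 px, about 10 um at SIM sampling) from the image itself; spot-scale
#' contrast is preserved because the blur radius far exceeds the filament
#' scale. The signed residual is kept by default: clipping negatives
#' would destroy the background noise statistics that the downstream
#' threshold is estimated from (set `clip = TRUE` for a non-negative
#' result).
#'
#' @param image image matrix.
#' @param gaussian_radius_px blur sigma in pixels.
#' @param clip clip negative residuals to zero.
#' @return background-homogenized matrix.
#' @export
homogenize_background <- function(image, gaussian_radius_px = 500,
                                  clip = FALSE) {
  assert_positive(gaussian_radius_px, "gaussian_radius_px")
  out <- image - gaussian_blur(image, gaussian_radius_px)
  if (clip) out <- pmax(out, 0)
  out
}

#' Richardson-Lucy deconvolution with a Gaussian PSF
#'
#' Iterative non-negative deconvolution; the iteration is stopped early
#' with a warning if the estimate norm starts to diverge.
#'
#' @param image non-negative image matrix.
#' @param psf_sigma_px Gaussian PSF sigma in pixels.
#' @param iterations iteration count (default 20).
#' @return deconvolved matrix.
#' @export
rl_deconvolve <- function(image, psf_sigma_px, iterations = 20) {
  assert_positive(psf_sigma_px, "psf_sigma_px")
  # RL requires non-negative data; a signed residual image is shifted up
  # by its minimum (an exact, invertible offset that survives as a flat
  # plateau under deconvolution)
  img <- if (min(image) < 0) image - min(image) else image
  est <- img
  prev_norm <- sum(est^2)
  for (it in seq_len(iterations)) {
    conv <- gaussian_blur(est, psf_sigma_px)
    ratio <- img / pmax(conv, 1e-12)
    est <- est * gaussian_blur(ratio, psf_sigma_px)
    nn <- sum(est^2)
    if (!is.finite(nn) || nn > 1e6 * max(prev_norm, 1e-12)) {
      rlang::warn(sprintf("deconvolution diverging at iteration %d; stopping", it))
      break
    }
    prev_norm <- nn
  }
  est
}

#' Threshold against background noise and erode isolated pixels
#'
#' Pixels below the background level plus 3x the standard deviation of a
#' cell-free background region are zeroed (for a zero-mean homogenized
#' background this is the plain 3-sigma noise cut); the binary support is
#' then cleaned with a 3x3 erosion-style operator that removes pixels
#' with fewer than two above-threshold 8-neighbours, killing the
#' isolated speckle that deconvolution makes of white noise while the
#' multi-pixel cores of real spots survive. Surviving pixels keep their
#' intensities.
#'
#' @param image image matrix.
#' @param background_roi logical mask of a cell-free area, or
#'   `c(row0, row1, col0, col1)` indices.
#' @param k threshold multiplier (default 3).
#' @param min_neighbours minimum above-threshold 8-neighbours to survive.
#' @return cleaned matrix.
#' @export
threshold_and_clean <- function(image, background_roi, k = 3,
                                min_neighbours = 2) {
  if (is.numeric(background_roi) && length(background_roi) == 4) {
    m <- matrix(FALSE, nrow(image), ncol(image))
    m[background_roi[1]:background_roi[2],
      background_roi[3]:background_roi[4]] <- TRUE
    background_roi <- m
  }
  abort_if(!any(background_roi), "background ROI is empty")
  vals <- image[background_roi]
  thr <- mean(vals) + k * stats::sd(vals)
  supp <- image >= thr
  nb <- EBImage::filter2(supp * 1, matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3))
  keep <- supp & nb >= min_neighbours - 0.5
  out <- image
  out[!keep] <- 0
  out
}

#' Detect spots as strict 8-neighbour local maxima with centroid refinement
#'
#' A pixel is a peak if it exceeds all eight direct neighbours; each peak
#' is refined to the intensity centroid of the 5x5-pixel region of
#' interest around it, and refined positions within one pixel of each
#' other are merged. Plateaus of exactly equal pixels have no strict
#' maximum and are skipped (first-in-scan-order tie-break applies only
#' through the merging step).
#'
#' @param image cleaned image matrix.
#' @param pixel_size_nm pixel size.
#' @param margin_px border margin excluded from detection.
#' @return tibble `x_nm`, `y_nm`, `intensity`.
#' @export
detect_peaks <- function(image, pixel_size_nm, margin_px = 2) {
  nr <- nrow(image); nc <- ncol(image)
  is_max <- matrix(TRUE, nr, nc)
  core_r <- 2:(nr - 1); core_c <- 2:(nc - 1)
  center <- image[core_r, core_c]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max[core_r, core_c] <- is_max[core_r, core_c] &
      (center > image[core_r + di, core_c + dj])
  }
  is_max[c(1, nr), ] <- FALSE; is_max[, c(1, nc)] <- FALSE
  is_max[image <= 0] <- FALSE
  if (margin_px > 0) {
    is_max[seq_len(min(margin_px, nr)), ] <- FALSE
    is_max[(nr - margin_px + 1):nr, ] <- FALSE
    is_max[, seq_len(min(margin_px, nc))] <- FALSE
    is_max[, (nc - margin_px + 1):nc] <- FALSE
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(x_nm = numeric(), y_nm = numeric(),
                          intensity = numeric()))
  }
  pts <- purrr::map_dfr(seq_len(nrow(idx)), function(q) {
    i <- idx[q, 1]; j <- idx[q, 2]
    ir <- max(1, i - 2):min(nr, i + 2)
    jr <- max(1, j - 2):min(nc, j + 2)
    w <- image[ir, jr]
    s <- sum(w)
    ci <- sum(ir * rowSums(w)) / s
    cj <- sum(jr * colSums(w)) / s
    tibble::tibble(x_nm = (cj - 0.5) * pixel_size_nm,
                   y_nm = (ci - 0.5) * pixel_size_nm,
                   intensity = image[i, j])
  })
  # merge refined duplicates within one pixel (keep the brighter)
  pts <- dplyr::arrange(pts, dplyr::desc(.data$intensity))
  keep <- rep(TRUE, nrow(pts))
  for (q in seq_len(nrow(pts))) {
    if (!keep[q]) next
    later <- which(keep & seq_len(nrow(pts)) > q)
    if (length(later) == 0) next
    d2 <- (pts$x_nm[later] - pts$x_nm[q])^2 + (pts$y_nm[later] - pts$y_nm[q])^2
    keep[later[d2 <= pixel_size_nm^2]] <- FALSE
  }
  pts[keep, ]
}

#' Pair head peaks and validate candidates by a tail peak
#'
#' All pairs of green (head) peaks separated by `d_min`-`d_max` become
#' minifilament candidates; a candidate is validated if some red (tail)
#' peak lies within `tail_radius_nm` of the pair midpoint. A head may
#' participate in several candidates (all-pairs rule); optionally,
#' conflicts are resolved greedily by tail distance.
#'
#' @param green_peaks,red_peaks tibbles with `x_nm`, `y_nm`.
#' @param d_min_nm,d_max_nm head-separation bounds (defaults 200/400 nm).
#' @param tail_radius_nm validation radius about the midpoint (50 nm).
#' @param resolve_conflicts if `TRUE`, each head is used at most once,
#'   assigning candidates greedily by increasing tail distance.
#' @return tibble of minifilament records: head and tail coordinates,
#'   `projected_length_nm`, `tail_dist_nm`, `validated`.
#' @export
pair_minifilaments <- function(green_peaks, red_peaks,
                               d_min_nm = 200, d_max_nm = 400,
                               tail_radius_nm = 50,
                               resolve_conflicts = FALSE) {
  ng <- nrow(green_peaks)
  empty <- tibble::tibble(head1_x = numeric(), head1_y = numeric(),
                          head2_x = numeric(), head2_y = numeric(),
                          center_x = numeric(), center_y = numeric(),
                          tail_x = numeric(), tail_y = numeric(),
                          projected_length_nm = numeric(),
                          tail_dist_nm = numeric(), validated = logical())
  if (ng < 2) return(empty)
  gx <- green_peaks$x_nm; gy <- green_peaks$y_nm
  d <- sqrt(outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2)
  cand <- which(upper.tri(d) & d >= d_min_nm & d <= d_max_nm, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  recs <- tibble::tibble(
    i = cand[, 1], j = cand[, 2],
    head1_x = gx[cand[, 1]], head1_y = gy[cand[, 1]],
    head2_x = gx[cand[, 2]], head2_y = gy[cand[, 2]],
    projected_length_nm = d[cand])
  recs$center_x <- (recs$head1_x + recs$head2_x) / 2
  recs$center_y <- (recs$head1_y + recs$head2_y) / 2
  if (nrow(red_peaks) > 0) {
    td <- sqrt(outer(recs$center_x, red_peaks$x_nm, "-")^2 +
                 outer(recs$center_y, red_peaks$y_nm, "-")^2)
    nearest <- apply(td, 1, which.min)
    recs$tail_dist_nm <- td[cbind(seq_len(nrow(recs)), nearest)]
    recs$tail_x <- red_peaks$x_nm[nearest]
    recs$tail_y <- red_peaks$y_nm[nearest]
  } else {
    recs$tail_dist_nm <- Inf
    recs$tail_x <- NA_real_; recs$tail_y <- NA_real_
  }
  recs$validated <- recs$tail_dist_nm <= tail_radius_nm
  if (resolve_conflicts) {
    recs <- dplyr::arrange(recs, .data$tail_dist_nm)
    used <- logical(ng)
    keep <- logical(nrow(recs))
    for (q in seq_len(nrow(recs))) {
      if (!recs$validated[q]) next
      if (used[recs$i[q]] || used[recs$j[q]]) next
      keep[q] <- TRUE
      used[recs$i[q]] <- TRUE; used[recs$j[q]] <- TRUE
    }
    recs <- recs[keep | !recs$validated, ]
  }
  dplyr::select(recs, -"i", -"j") |>
    dplyr::relocate("head1_x", "head1_y", "head2_x", "head2_y",
                    "center_x", "center_y", "tail_x", "tail_y",
                    "projected_length_nm", "tail_dist_nm", "validated")
}

#' Full minifilament detection chain on a two-channel image
#'
#' Background homogenization, Richardson-Lucy deconvolution, noise
#' thresholding and peak detection on both channels, followed by pairing
#' and tail validation. Analysis is restricted to the image interior by a
#' margin of `d_max_nm`.
#'
#' @param green,red image matrices (heads / tails).
#' @param pixel_size_nm pixel size.
#' @param psf_sigma_nm PSF sigma for deconvolution.
#' @param background_roi background region for thresholding (see
#'   [threshold_and_clean()]).
#' @param homogenize_radius_px background blur radius.
#' @param iterations deconvolution iterations.
#' @param ... passed to [pair_minifilaments()].
#' @return validated record tibble (see [pair_minifilaments()]).
#' @export
detect_minifilaments <- function(green, red, pixel_size_nm, psf_sigma_nm,
                                 background_roi,
                                 homogenize_radius_px = 500,
                                 iterations = 20, ...) {
  process <- function(img) {
    img |>
      homogenize_background(homogenize_radius_px) |>
      rl_deconvolve(psf_sigma_nm / pixel_size_nm, iterations) |>
      threshold_and_clean(background_roi) |>
      detect_peaks(pixel_size_nm,
                   margin_px = ceiling(400 / pixel_size_nm))
  }
  pair_minifilaments(process(green), process(red), ...)
}

#' Per-cell projected-length statistics
#'
#' @param records validated minifilament records with a `cell` column (a
#'   single cell is assumed if absent).
#' @param min_records flag cells with fewer records than this.
#' @return tibble per cell: n, mean/SD projected length, low-count flag.
#' @export
projected_length_stats <- function(records, min_records = 10) {
  abort_if(nrow(records) == 0, "no validated minifilament records")
  if (!"cell" %in% names(records)) records$cell <- 1L
  records |>
    dplyr::filter(.data$validated) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_projected_nm = mean(.data$projected_length_nm),
                     sd_projected_nm = stats::sd(.data$projected_length_nm),
                     .groups = "drop") |>
    dplyr::mutate(low_count = .data$n < min_records)
}

#' Minifilament angle from its projected length
#'
#' Assuming the true minifilament length does not change, the angle to
#' the membrane plane is `acos(L_proj / L_ref)`.
#'
#' @param l_proj_nm projected length (nm).
#' @param l_ref_nm reference (true) length; default 317 nm, the
#'   stress-fiber value (330 nm from electron microscopy is the
#'   documented alternative).
#' @return angle in degrees.
#' @export
angle_from_projection <- function(l_proj_nm, l_ref_nm = 317) {
  abort_if(any(l_proj_nm <= 0), "projected length must be positive")
  abort_if(any(l_proj_nm > l_ref_nm),
           "projected length exceeds the reference length; use a larger l_ref_nm")
  acos(l_proj_nm / l_ref_nm) * 180 / pi
}

#' Relative tension change from an orientation change
#'
#' Under the simplest model in which every minifilament contributes to
#' in-plane tension proportionally to the cosine of its angle to the
#' membrane, a change from `theta_before` to `theta_after` changes
#' tension by `100 * (cos(after) / cos(before) - 1)` percent -- which at
#' fixed reference length equals the percent change in projected length.
#'
#' @param theta_before_deg,theta_after_deg angles in degrees, in [0, 90).
#' @return percent change in tension.
#' @export
tension_change_from_angles <- function(theta_before_deg, theta_after_deg) {
  abort_if(any(c(theta_before_deg, theta_after_deg) < 0) ||
             any(c(theta_before_deg, theta_after_deg) >= 90),
           "angles must lie in [0, 90) degrees")
  100 * (cos(theta_after_deg * pi / 180) /
           cos(theta_before_deg * pi / 180) - 1)
}
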