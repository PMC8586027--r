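#' Confocal cortical-intensity quantification
#'
#' Background subtraction (rolling-ball top-hat), two independent
#' segmentation routes (noise-threshold and edge/watershed), per-cell
#' selection of the segmentation whose contour carries the most signal,
#' cortical-band intensity measurement, and unspecific-staining
#' correction.
#'
#' @name confocal_quant
NULL

#' Rolling-ball background subtraction (morphological top-hat)
#'
#' The background under each pixel is estimated by a grayscale opening
#' with a disc structuring element of the given radius (the flat
#' equivalent of rolling a ball under the intensity surface) and
#' subtracted. The radius must be large relative to the structure of
#' interest (the cortex is typically ~8 px wide; default radius 50 px),
#' otherwise the structure itself is attenuated.
#'
#' @param image image matrix.
#' @param radius_px ball radius (pixels).
#' @return background-subtracted matrix (>= 0).
#' @export
subtract_background_rollingball <- function(image, radius_px = 50) {
  assert_positive(radius_px, "radius_px")
  size <- 2 * floor(radius_px) + 1
  kern <- EBImage::makeBrush(size, shape = "disc")
  # EBImage grayscale morphology operates on intensities in [0, 1]
  lo <- min(image)
  rng <- max(max(image) - lo, 1e-300)
  shifted <- (image - lo) / rng
  bg <- EBImage::opening(shifted, kern)
  pmax(shifted - bg, 0) * rng
}

#' Threshold segmentation against an empty region
#'
#' The threshold is the mean plus one standard deviation of the pixel
#' values in a cell-free region; connected components above a minimum
#' area become candidate masks.
#'
#' @param image image matrix (background-subtracted).
#' @param empty_region logical mask or `c(row0, row1, col0, col1)` of a
#'   truly cell-free area.
#' @param min_area_px minimum component area.
#' @return list of logical candidate masks (attribute
#'   `provenance = "threshold"`).
#' @export
segment_threshold <- function(image, empty_region, min_area_px = 100) {
  abort_if(missing(empty_region) || is.null(empty_region),
           "an empty (cell-free) region is required")
  if (is.numeric(empty_region) && length(empty_region) == 4) {
    m <- matrix(FALSE, nrow(image), ncol(image))
    m[empty_region[1]:empty_region[2], empty_region[3]:empty_region[4]] <- TRUE
    empty_region <- m
  }
  vals <- image[empty_region]
  thr <- mean(vals) + stats::sd(vals)
  bin <- image > thr
  # a binary opening removes noise speckle before components are labelled
  bin <- EBImage::opening(bin, EBImage::makeBrush(3, "box")) > 0
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  keep_masks(lab, min_area_px, "threshold")
}

keep_masks <- function(lab, min_area_px, provenance, clear_border = TRUE) {
  ids <- setdiff(unique(as.vector(lab)), 0)
  masks <- purrr::map(ids, ~ lab == .x)
  masks <- purrr::keep(masks, ~ sum(.x) >= min_area_px)
  if (clear_border) {
    # objects clipped by the field of view cannot be quantified reliably
    masks <- purrr::discard(masks, function(m) {
      any(m[c(1, nrow(m)), ]) || any(m[, c(1, ncol(m))])
    })
  }
  attr(masks, "provenance") <- provenance
  masks
}

#' Edge-based segmentation (Sobel + watershed)
#'
#' Cell edges are detected with a Sobel filter; the gradient magnitude is
#' thresholded, holes filled, small objects removed, and touching cells
#' split by a watershed on the distance map.
#'
#' @param image image matrix.
#' @param k edge threshold: gradient magnitudes above mean + k SD count
#'   as edges (an absolute criterion, so a featureless image yields no
#'   edges).
#' @param min_area_px minimum component area.
#' @return list of logical candidate masks (attribute
#'   `provenance = "edges"`).
#' @export
segment_edges <- function(image, k = 3, min_area_px = 100) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  gx <- EBImage::filter2(image, sx)
  gy <- EBImage::filter2(image, t(sx))
  grad <- sqrt(gx^2 + gy^2)
  edges <- grad > mean(grad) + k * stats::sd(grad)
  edges <- EBImage::dilate(edges, EBImage::makeBrush(3, "box"))
  filled <- EBImage::fillHull(edges)
  filled <- EBImage::erode(filled, EBImage::makeBrush(3, "box"))
  lab0 <- EBImage::bwlabel(filled)
  # drop undersized blobs before watershed splitting
  sizes <- table(as.vector(lab0))
  for (id in names(sizes)) {
    if (id != "0" && sizes[[id]] < min_area_px) lab0[lab0 == as.integer(id)] <- 0
  }
  mask <- lab0 > 0
  if (!any(mask)) {
    out <- list(); attr(out, "provenance") <- "edges"; return(out)
  }
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 1)
  keep_masks(lab, min_area_px, "edges")
}

mask_outline <- function(mask) {
  mask & !EBImage::erode(mask, EBImage::makeBrush(3, "box"))
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Choose the best segmentation per cell across methods
#'
#' Candidates from all methods are grouped by centroid proximity; within
#' each group the candidate whose cortex outline carries the highest
#' total image intensity wins, and its provenance is recorded. The
#' outer/inner band boundaries are those of the mask dilated by a 5 px
#' and eroded by a 3 px structuring element.
#'
#' @param candidates list of candidate-mask lists (each as returned by a
#'   `segment_*` function).
#' @param image the intensity image used for scoring.
#' @param grouping_distance_px centroid grouping distance (default 20).
#' @return tibble of class `cell_segmentation`: one row per cell with
#'   centroid, provenance, contour score, and list-columns `mask`,
#'   `outline`, `band` (the 5-px-dilated minus 3-px-eroded band).
#' @export
select_best_segmentation <- function(candidates, image,
                                     grouping_distance_px = 20) {
  flat <- purrr::map_dfr(candidates, function(cl) {
    if (length(cl) == 0) return(NULL)
    prov <- attr(cl, "provenance") %||% "unknown"
    purrr::map_dfr(cl, function(m) {
      ctr <- mask_centroid(m)
      ol <- mask_outline(m)
      tibble::tibble(row = ctr[1], col = ctr[2], provenance = prov,
                     score = sum(image[ol]), mask = list(m),
                     outline = list(ol))
    })
  })
  abort_if(nrow(flat) == 0, "no segmentation candidates")
  # greedy grouping by centroid distance
  group <- integer(nrow(flat))
  g <- 0
  for (q in seq_len(nrow(flat))) {
    if (group[q] != 0) next
    g <- g + 1
    group[q] <- g
    if (q < nrow(flat)) {
      rest <- (q + 1):nrow(flat)
      d <- sqrt((flat$row[rest] - flat$row[q])^2 +
                  (flat$col[rest] - flat$col[q])^2)
      group[rest[group[rest] == 0 & d <= grouping_distance_px]] <- g
    }
  }
  flat$group <- group
  best <- flat |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  best$band <- purrr::map(best$mask, function(m) {
    outer_b <- EBImage::dilate(m, EBImage::makeBrush(5, "disc"))
    inner_b <- EBImage::erode(m, EBImage::makeBrush(3, "disc"))
    outer_b & !inner_b
  })
  out <- dplyr::select(best, -"group")
  class(out) <- c("cell_segmentation", class(out))
  out
}

#' Mean cortical intensity in a band centred on the cell outline
#'
#' The band is the set of pixels within half the band thickness of the
#' segmented cortex outline (default 8 px thick). Bands clipped by the
#' image border are measured on the available pixels and flagged.
#'
#' @param image intensity image.
#' @param segmentation a [select_best_segmentation()] tibble.
#' @param band_px band thickness (default 8).
#' @return tibble per cell: `mean_cortical_intensity`, `band_area_px`,
#'   `clipped`.
#' @export
cortical_band_intensity <- function(image, segmentation, band_px = 8) {
  purrr::map_dfr(seq_len(nrow(segmentation)), function(k) {
    ol <- segmentation$outline[[k]]
    half <- max(1, round(band_px / 2))
    band <- EBImage::dilate(ol, EBImage::makeBrush(2 * half + 1, "disc"))
    touches <- any(band[c(1, nrow(band)), ]) || any(band[, c(1, ncol(band))])
    tibble::tibble(cell = k,
                   mean_cortical_intensity = mean(image[band]),
                   band_area_px = sum(band),
                   clipped = touches)
  })
}

#' Correct measured intensities for unspecific staining
#'
#' Subtracts the mean of control measurements (secondary antibody only)
#' from each value; negative corrected values are allowed and flagged.
#'
#' @param values measured per-cell intensities.
#' @param control_values control (unspecific) per-cell intensities.
#' @return tibble `value`, `corrected`, `negative`.
#' @export
correct_unspecific <- function(values, control_values) {
  abort_if(length(control_values) == 0, "empty control measurements")
  corr <- values - mean(control_values)
  tibble::tibble(value = values, corrected = corr, negative = corr < 0)
}
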