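#' Cortex detection, straightening and transverse-profile statistics
#'
#' The cortical band in a rendered super-resolution image is traced by
#' refining a coarse seed polyline to the ridge of the actin channel,
#' fitting a cubic spline, sampling intensity along the spline normals
#' (straightening), and analysing the straightened image in bins along the
#' cortex. Each bin yields per-channel peak position and FWHM, from which
#' the peak-to-peak distance and the signed cytoplasmic overhang follow.
#'
#' The transverse axis is signed, positive toward the cytoplasm.
#'
#' @name cortex_profile
NULL

#' Circle seed polyline for roughly circular cells
#'
#' @param center,radius circle in nm.
#' @param n number of seed points.
#' @param arc angular range in radians.
#' @return n x 2 matrix of seed points (nm).
#' @export
circle_seed <- function(center, radius, n = 72, arc = c(0, 2 * pi)) {
  th <- seq(arc[1], arc[2], length.out = n + 1)[seq_len(n)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

seed_normals <- function(seeds) {
  n <- nrow(seeds)
  nxt <- seeds[c(2:n, n), ] - seeds[c(1, 1:(n - 1)), ]
  len <- sqrt(rowSums(nxt^2))
  tang <- nxt / pmax(len, 1e-9)
  cbind(-tang[, 2], tang[, 1])   # tangent rotated +90 degrees
}

#' Detect the cortex ridge from a rendered actin image
#'
#' Each seed point is moved along its local normal to the transverse
#' intensity maximum of the actin channel (with parabolic sub-pixel
#' refinement); points whose refinement diverges or that sit over a hole
#' in the band are dropped, and a cubic smoothing spline is fitted through
#' the survivors, parameterised by arc length. The inward normal is
#' oriented toward the cytoplasm: by default, toward the centroid of the
#' refined points (appropriate for closed, convex cell outlines), or
#' explicitly via `cytoplasm_side`.
#'
#' @param image A rendered actin image ([render_localizations()]).
#' @param seeds n x 2 matrix of seed points (nm) roughly on the cortex,
#'   e.g. from [circle_seed()].
#' @param search_halfwidth_nm half-width of the transverse search window.
#' @param cytoplasm_side `"auto"` (toward the seed centroid), `"left"` or
#'   `"right"` of the direction of travel along the contour.
#' @param spar smoothing parameter passed to [stats::smooth.spline()].
#' @return An object of class `cortex_contour`.
#' @export
detect_cortex <- function(image, seeds, search_halfwidth_nm = 500,
                          cytoplasm_side = "auto", spar = 0.3) {
  seeds <- as.matrix(seeds)
  abort_if(nrow(seeds) < 4, "need at least 4 seed points")
  p <- pixel_size_of(image)
  normals <- seed_normals(seeds)
  offs <- seq(-search_halfwidth_nm, search_halfwidth_nm, by = p)
  refined <- matrix(NA_real_, nrow(seeds), 2)
  for (i in seq_len(nrow(seeds))) {
    xs <- seeds[i, 1] + offs * normals[i, 1]
    ys <- seeds[i, 2] + offs * normals[i, 2]
    prof <- interp_bilinear(image, xs, ys)
    if (all(is.na(prof)) || max(prof, na.rm = TRUE) <= 0) next  # hole in band
    k <- which.max(prof)
    if (k == 1 || k == length(prof) || is.na(prof[k - 1]) || is.na(prof[k + 1]))
      next
    sub <- parabolic_offset(prof[k - 1], prof[k], prof[k + 1])
    shift <- offs[k] + sub * p
    if (abs(shift) > search_halfwidth_nm) next
    refined[i, ] <- seeds[i, ] + shift * normals[i, ]
  }
  ok <- stats::complete.cases(refined)
  if (sum(ok) < nrow(seeds)) {
    rlang::warn(sprintf("%d seed point(s) dropped during ridge refinement",
                        nrow(seeds) - sum(ok)))
  }
  abort_if(sum(ok) < 4, "fewer than 4 seed points survived refinement")
  pts <- refined[ok, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  fx <- stats::smooth.spline(s, pts[, 1], spar = spar)
  fy <- stats::smooth.spline(s, pts[, 2], spar = spar)

  side_sign <- switch(cytoplasm_side,
    auto = {
      ctr <- colMeans(pts)
      mid <- floor(nrow(pts) / 2)
      nrm <- seed_normals(pts)[mid, ]
      if (sum((ctr - pts[mid, ]) * nrm) >= 0) 1 else -1
    },
    left = 1, right = -1,
    rlang::abort("cytoplasm_side must be 'auto', 'left' or 'right'"))

  structure(list(points = pts, arc = s, fx = fx, fy = fy,
                 side_sign = side_sign, length_nm = max(s)),
            class = "cortex_contour")
}

contour_eval <- function(contour, s) {
  x <- stats::predict(contour$fx, s)$y
  y <- stats::predict(contour$fy, s)$y
  dx <- stats::predict(contour$fx, s, deriv = 1)$y
  dy <- stats::predict(contour$fy, s, deriv = 1)$y
  len <- sqrt(dx^2 + dy^2)
  tang <- cbind(dx, dy) / pmax(len, 1e-12)
  normal <- contour$side_sign * cbind(-tang[, 2], tang[, 1])
  list(xy = cbind(x, y), normal = normal)
}

#' Straighten the cortex along its spline normals
#'
#' Samples each channel by bilinear interpolation along lines normal to
#' the fitted contour, at the rendering pixel pitch. Rows are arc-length
#' positions; columns the signed transverse axis (positive toward the
#' cytoplasm). Rows whose normal leaves the image are flagged incomplete
#' and excluded downstream. For a circular band of radius R the residual
#' curvature-induced width error is below w^2/(8R) over a half-width w.
#'
#' @param images a single rendered image or named list of per-channel
#'   rendered images sharing grid and pixel size.
#' @param contour a [detect_cortex()] result.
#' @param half_width_nm transverse half-width to sample (should exceed the
#'   expected FWHM).
#' @return list of class `straightened_cortex`: per-channel matrices,
#'   `axis_nm`, `arc_nm`, logical `complete` per row.
#' @export
straighten <- function(images, contour, half_width_nm = 500) {
  if (inherits(images, "rendered_image")) images <- list(images)
  p <- pixel_size_of(images[[1]])
  s <- seq(0, contour$length_nm, by = p)
  ev <- contour_eval(contour, s)
  axis <- seq(-half_width_nm, half_width_nm, by = p)
  chans <- purrr::map(images, function(img) {
    m <- matrix(NA_real_, length(s), length(axis))
    for (i in seq_along(s)) {
      m[i, ] <- interp_bilinear(img,
                                ev$xy[i, 1] + axis * ev$normal[i, 1],
                                ev$xy[i, 2] + axis * ev$normal[i, 2])
    }
    m
  })
  complete <- Reduce(`&`, purrr::map(chans, ~ stats::complete.cases(.x)))
  structure(list(channels = chans, axis_nm = axis, arc_nm = s,
                 complete = complete),
            class = "straightened_cortex")
}

#' Bin straightened profiles along the cortex
#'
#' Profiles are averaged within consecutive arc-length bins (default
#' 200 nm, i.e. 20 rendering pixels of 10 nm). Bins containing flagged
#' incomplete rows are excluded; an incomplete trailing bin is dropped.
#'
#' @param straightened a [straighten()] result.
#' @param bin_width_nm bin width along the cortex.
#' @return tibble with columns `bin`, `arc_center_nm`, `channel`, and a
#'   `profile` list-column of tibbles (`position_nm`, `intensity`).
#' @export
bin_profiles <- function(straightened, bin_width_nm = 200) {
  s <- straightened$arc_nm
  pitch <- s[2] - s[1]
  rows_per_bin <- max(1L, round(bin_width_nm / pitch))
  n_bins <- floor(length(s) / rows_per_bin)
  abort_if(n_bins < 1, "no complete bin fits along the contour")
  out <- purrr::map_dfr(seq_len(n_bins), function(b) {
    rows <- ((b - 1) * rows_per_bin + 1):(b * rows_per_bin)
    if (!all(straightened$complete[rows])) return(NULL)
    purrr::imap_dfr(straightened$channels, function(m, ch) {
      tibble::tibble(
        bin = b,
        arc_center_nm = mean(s[rows]),
        channel = if (is.character(ch)) ch else paste0("ch", ch),
        profile = list(tibble::tibble(position_nm = straightened$axis_nm,
                                      intensity = colMeans(m[rows, , drop = FALSE])))
      )
    })
  })
  out
}

#' Peak position and FWHM of a transverse profile
#'
#' Background is the mean of the two per-side medians of the outer 20% of
#' samples; the peak is the background-subtracted maximum with parabolic
#' sub-pixel refinement, and the FWHM interval is bounded by the innermost
#' half-maximum crossings bracketing the peak, located by linear
#' interpolation. Profiles without an interior peak above background or
#' truncated before a crossing are rejected with a reason code.
#'
#' @param position_nm,intensity numeric vectors (strictly increasing axis).
#' @return list: `ok`, `reason`, `peak_nm`, `fwhm_lo_nm`, `fwhm_hi_nm`,
#'   `fwhm_nm`, `peak_intensity`.
#' @export
measure_fwhm <- function(position_nm, intensity) {
  n <- length(position_nm)
  reject <- function(reason) list(ok = FALSE, reason = reason,
                                  peak_nm = NA_real_, fwhm_lo_nm = NA_real_,
                                  fwhm_hi_nm = NA_real_, fwhm_nm = NA_real_,
                                  peak_intensity = NA_real_)
  if (n < 7 || anyNA(intensity)) return(reject("too_short_or_na"))
  k_out <- max(1L, floor(0.2 * n))
  bg <- mean(c(stats::median(intensity[seq_len(k_out)]),
               stats::median(intensity[(n - k_out + 1):n])))
  y <- intensity - bg
  k <- which.max(y)
  if (k == 1 || k == n) return(reject("no_interior_peak"))
  if (y[k] <= 0) return(reject("below_background"))
  sub <- parabolic_offset(y[k - 1], y[k], y[k + 1])
  peak <- position_nm[k] + sub * (position_nm[min(k + 1, n)] - position_nm[k])
  half <- y[k] / 2

  cross_left <- NA_real_
  for (i in seq(k - 1, 1)) {
    if (y[i] <= half && y[i + 1] > half) {
      f <- (half - y[i]) / (y[i + 1] - y[i])
      cross_left <- position_nm[i] + f * (position_nm[i + 1] - position_nm[i])
      break
    }
  }
  cross_right <- NA_real_
  for (i in seq(k, n - 1)) {
    if (y[i] > half && y[i + 1] <= half) {
      f <- (y[i] - half) / (y[i] - y[i + 1])
      cross_right <- position_nm[i] + f * (position_nm[i + 1] - position_nm[i])
      break
    }
  }
  if (is.na(cross_left) || is.na(cross_right)) return(reject("truncated_profile"))
  list(ok = TRUE, reason = NA_character_, peak_nm = peak,
       fwhm_lo_nm = cross_left, fwhm_hi_nm = cross_right,
       fwhm_nm = cross_right - cross_left, peak_intensity = y[k])
}

#' Measure all binned profiles
#'
#' @param bins a [bin_profiles()] tibble.
#' @return the same tibble with unnested measurement columns.
#' @export
measure_bins <- function(bins) {
  meas <- purrr::map(bins$profile,
                     ~ measure_fwhm(.x$position_nm, .x$intensity))
  dplyr::bind_cols(
    dplyr::select(bins, -"profile"),
    purrr::map_dfr(meas, ~ tibble::as_tibble(.x[c("ok", "reason", "peak_nm",
                                                  "fwhm_lo_nm", "fwhm_hi_nm",
                                                  "fwhm_nm")]))
  )
}

#' Signed peak-to-peak distance between two channels
#'
#' Target peak position minus actin peak position on the signed transverse
#' axis; positive values place the target deeper in the cytoplasm.
#'
#' @param actin,target measurement lists from [measure_fwhm()].
#' @return signed distance in nm (NA if either side was rejected).
#' @export
peak_to_peak <- function(actin, target) {
  if (!isTRUE(actin$ok) || !isTRUE(target$ok)) return(NA_real_)
  target$peak_nm - actin$peak_nm
}

#' Signed cytoplasmic overhang from two FWHM intervals
#'
#' With the actin FWHM interval `[a_lo, a_hi]` and the target interval
#' `[t_lo, t_hi]` on the signed transverse axis (hi = cytoplasmic edge),
#' the overhang is `100 * (t_hi - a_hi) / (t_hi - t_lo)`: the percentage
#' of the target FWHM protruding beyond the actin FWHM into the
#' cytoplasm. It is negative when the target's cytoplasmic edge is
#' retracted toward the membrane (as for membrane-linked proteins such as
#' moesin).
#'
#' @param a_lo,a_hi,t_lo,t_hi interval bounds in nm.
#' @return signed overhang in percent.
#' @export
overhang_interval <- function(a_lo, a_hi, t_lo, t_hi) {
  abort_if(t_hi <= t_lo, "degenerate target FWHM interval")
  abort_if(a_hi <= a_lo, "degenerate actin FWHM interval")
  100 * (t_hi - a_hi) / (t_hi - t_lo)
}

#' Symmetric two-sided non-overlap (alternative overhang metric)
#'
#' Percentage of the target FWHM interval lying outside the actin FWHM
#' interval on either side. Off by default in the pipeline.
#'
#' @inheritParams overhang_interval
#' @export
nonoverlap_interval <- function(a_lo, a_hi, t_lo, t_hi) {
  abort_if(t_hi <= t_lo, "degenerate target FWHM interval")
  inside <- max(0, min(t_hi, a_hi) - max(t_lo, a_lo))
  100 * (1 - inside / (t_hi - t_lo))
}

#' Per-bin overhang table for a two-channel measurement
#'
#' @param measured a [measure_bins()] tibble containing exactly two
#'   channels.
#' @param actin_channel name of the actin (reference) channel.
#' @return tibble with one row per bin: FWHMs, peak-to-peak, overhang.
#' @export
profile_overhang <- function(measured, actin_channel = "actin") {
  chans <- unique(measured$channel)
  abort_if(length(chans) != 2, "need exactly two channels")
  abort_if(!actin_channel %in% chans,
           paste0("channel '", actin_channel, "' not present"))
  target_channel <- setdiff(chans, actin_channel)
  wide <- measured |>
    tidyr::pivot_wider(names_from = "channel",
                       values_from = c("ok", "peak_nm", "fwhm_lo_nm",
                                       "fwhm_hi_nm", "fwhm_nm", "reason"))
  a <- function(col) wide[[paste0(col, "_", actin_channel)]]
  t_ <- function(col) wide[[paste0(col, "_", target_channel)]]
  ok <- a("ok") & t_("ok")
  tibble::tibble(
    bin = wide$bin,
    arc_center_nm = wide$arc_center_nm,
    accepted = ok,
    actin_fwhm_nm = a("fwhm_nm"),
    target_fwhm_nm = t_("fwhm_nm"),
    peak_to_peak_nm = ifelse(ok, t_("peak_nm") - a("peak_nm"), NA_real_),
    overhang_pct = ifelse(
      ok,
      100 * (t_("fwhm_hi_nm") - a("fwhm_hi_nm")) / t_("fwhm_nm"),
      NA_real_)
  )
}

#' Aggregate per-bin measurements to a per-cell result
#'
#' @param bin_table a [profile_overhang()] tibble.
#' @param min_bins minimum number of accepted bins (default 3).
#' @param center `"mean"` (default) or `"median"` across bins.
#' @return one-row tibble of class `overhang_result` with the per-bin
#'   table in attribute `bins`.
#' @export
aggregate_cell <- function(bin_table, min_bins = 3, center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else stats::median
  acc <- dplyr::filter(bin_table, .data$accepted)
  abort_if(nrow(acc) < min_bins,
           sprintf("only %d accepted bin(s); at least %d required",
                   nrow(acc), min_bins))
  out <- tibble::tibble(
    n_bins = nrow(acc),
    n_rejected = sum(!bin_table$accepted),
    actin_fwhm_nm = fun(acc$actin_fwhm_nm),
    target_fwhm_nm = fun(acc$target_fwhm_nm),
    peak_to_peak_nm = fun(acc$peak_to_peak_nm),
    overhang_pct = fun(acc$overhang_pct)
  )
  attr(out, "bins") <- bin_table
  class(out) <- c("overhang_result", class(out))
  out
}

#' Worst-case FWHM inflation from out-of-plane cortex curvature
#'
#' For a spherical cell of radius R imaged with a focal slab of the given
#' thickness centred on the equator, out-of-focus portions of the shell
#' project inward by at most `R - sqrt(R^2 - (slab/2)^2)`; assuming the
#' worst case on both edges of the profile, the measured FWHM is inflated
#' by at most twice that.
#'
#' @param cell_radius_nm cell radius (nm).
#' @param slab_thickness_nm focal-plane thickness (nm).
#' @return upper bound on the FWHM broadening (nm).
#' @export
curvature_broadening_bound <- function(cell_radius_nm, slab_thickness_nm) {
  assert_positive(cell_radius_nm, "cell_radius_nm")
  abort_if(slab_thickness_nm < 0, "slab thickness must be >= 0")
  abort_if(cell_radius_nm <= slab_thickness_nm / 2,
           "cell radius must exceed half the slab thickness")
  2 * (cell_radius_nm -
         sqrt(cell_radius_nm^2 - (slab_thickness_nm / 2)^2))
}

#' End-to-end overhang measurement on a two-channel rendered scene
#'
#' Convenience chain: detect the cortex on the actin channel, straighten
#' both channels, bin, measure, and aggregate to a per-cell result.
#'
#' @param actin_image,target_image rendered per-channel images.
#' @param seeds seed polyline for [detect_cortex()].
#' @param half_width_nm transverse half-width.
#' @param bin_width_nm arc bin width.
#' @param ... passed on to [detect_cortex()].
#' @return an `overhang_result` (see [aggregate_cell()]).
#' @export
measure_cortex_overhang <- function(actin_image, target_image, seeds,
                                    half_width_nm = 500, bin_width_nm = 200,
                                    ...) {
  contour <- detect_cortex(actin_image, seeds, ...)
  st <- straighten(list(actin = actin_image, target = target_image),
                   contour, half_width_nm)
  bins <- bin_profiles(st, bin_width_nm)
  measured <- measure_bins(bins)
  aggregate_cell(profile_overhang(measured, "actin"))
}
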