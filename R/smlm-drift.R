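#' Fiducial-bead tracking for drift correction
#'
#' For each seed position, the nearest localization within the search
#' radius is assigned to that bead in every frame; gaps are filled by
#' linear interpolation, and beads found in fewer than half the frames
#' are dropped with a warning.
#'
#' @param table localization tibble (`frame`, `x`, `y` in nm).
#' @param seeds k x 2 matrix of approximate bead positions (nm).
#' @param search_radius_nm assignment radius.
#' @return tibble `bead`, `frame`, `x`, `y` (one row per bead and frame).
#' @export
track_fiducials <- function(table, seeds, search_radius_nm = 500) {
  seeds <- as.matrix(seeds)
  abort_if(nrow(seeds) < 1, "need at least one bead seed")
  assert_positive(search_radius_nm, "search_radius_nm")
  frames <- seq(min(table$frame), max(table$frame))
  tracks <- purrr::map(seq_len(nrow(seeds)), function(k) {
    near <- dplyr::filter(
      table,
      (.data$x - seeds[k, 1])^2 + (.data$y - seeds[k, 2])^2 <= search_radius_nm^2)
    if (nrow(near) == 0) return(NULL)
    obs <- near |>
      dplyr::mutate(d2 = (.data$x - seeds[k, 1])^2 + (.data$y - seeds[k, 2])^2) |>
      dplyr::group_by(.data$frame) |>
      dplyr::slice_min(.data$d2, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    if (nrow(obs) < 0.5 * length(frames)) {
      rlang::warn(sprintf("bead %d present in %.0f%% of frames; dropped",
                          k, 100 * nrow(obs) / length(frames)))
      return(NULL)
    }
    tibble::tibble(
      bead = k, frame = frames,
      x = stats::approx(obs$frame, obs$x, xout = frames, rule = 2)$y,
      y = stats::approx(obs$frame, obs$y, xout = frames, rule = 2)$y)
  })
  tracks <- dplyr::bind_rows(tracks)
  abort_if(nrow(tracks) == 0,
           "no bead could be tracked; consider drift_rcc() instead")
  tracks
}

moving_average <- function(v, window) {
  if (window <= 1) return(v)
  k <- rep(1 / window, window)
  n <- length(v)
  pad <- window  # replicate edges so the average is defined everywhere
  vv <- c(rep(v[1], pad), v, rep(v[n], pad))
  sm <- stats::filter(vv, k, sides = 2)
  as.numeric(sm[pad + seq_len(n)])
}

#' Per-frame drift from bead tracks
#'
#' Drift at each frame is the mean over beads of the displacement from
#' their first-frame position, smoothed with a moving average. An
#' SD-weighted combination across beads is available via `weights`.
#'
#' @param tracks a [track_fiducials()] tibble.
#' @param smooth_window moving-average window in frames (default 50).
#' @param weights `"equal"` (default) or `"inverse_variance"` across beads.
#' @return drift tibble `frame`, `dx`, `dy` (nm); first frame is (0, 0)
#'   up to smoothing.
#' @export
drift_from_beads <- function(tracks, smooth_window = 50,
                             weights = c("equal", "inverse_variance")) {
  weights <- match.arg(weights)
  disp <- tracks |>
    dplyr::group_by(.data$bead) |>
    # anchor on the mean over the first window rather than the raw first
    # frame, so the zero reference is not contaminated by bead jitter
    dplyr::mutate(ux = .data$x - mean(.data$x[seq_len(min(smooth_window,
                                                          dplyr::n()))]),
                  uy = .data$y - mean(.data$y[seq_len(min(smooth_window,
                                                          dplyr::n()))]),
                  w = switch(weights,
                             equal = 1,
                             inverse_variance = 1 / max(stats::var(.data$x - moving_average(.data$x, 101)), 1e-6))) |>
    dplyr::ungroup()
  drift <- disp |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(dx = stats::weighted.mean(.data$ux, .data$w),
                     dy = stats::weighted.mean(.data$uy, .data$w),
                     .groups = "drop") |>
    dplyr::arrange(.data$frame)
  drift$dx <- moving_average(drift$dx, smooth_window)
  drift$dy <- moving_average(drift$dy, smooth_window)
  drift
}

hist2d_counts <- function(x, y, extent, bin_nm) {
  nc <- max(1L, ceiling((extent[2] - extent[1]) / bin_nm))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / bin_nm))
  j <- pmin(pmax(floor((x - extent[1]) / bin_nm) + 1L, 1L), nc)
  i <- pmin(pmax(floor((y - extent[3]) / bin_nm) + 1L, 1L), nr)
  m <- matrix(tabulate((j - 1L) * nr + i, nbins = nr * nc), nr, nc)
  m
}

# Circular cross-correlation shift of B relative to A (in bins), with
# 3-point parabolic sub-bin refinement. Positive shift means B is A
# displaced toward larger coordinates.
xcorr_shift <- function(A, B) {
  FA <- stats::fft(A); FB <- stats::fft(B)
  C <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE))
  k <- which.max(C)
  nr <- nrow(C); nc <- ncol(C)
  i0 <- ((k - 1) %% nr) + 1
  j0 <- ((k - 1) %/% nr) + 1
  wrap <- function(idx, n) ifelse(idx - 1 > n / 2, idx - 1 - n, idx - 1)
  ip <- function(i) ((i - 1) %% nr) + 1
  jp <- function(j) ((j - 1) %% nc) + 1
  di <- parabolic_offset(C[ip(i0 - 1), j0], C[i0, j0], C[ip(i0 + 1), j0])
  dj <- parabolic_offset(C[i0, jp(j0 - 1)], C[i0, j0], C[i0, jp(j0 + 1)])
  c(dx = wrap(j0, nc) + dj, dy = wrap(i0, nr) + di)
}

#' Drift estimation by cross-correlation of temporal windows (RCC)
#'
#' The acquisition is divided into consecutive windows of 2000 frames;
#' the localizations of each window (optionally restricted to a cortical
#' region of interest, which concentrates the correlation signal on real
#' structure) are rendered into a 2D histogram with 20 nm sub-pixels.
#' Successive window histograms are cross-correlated; the correlation
#' peak, refined by a 3-point parabolic fit, gives the shift between
#' windows. Cumulative shifts are assigned to window midpoints and
#' interpolated to every frame with a cubic spline. An all-pairs
#' least-squares mode (`pairs = "all"`) uses every window pair for
#' redundancy.
#'
#' @param table localization tibble (`frame`, `x`, `y` in nm).
#' @param window_frames frames per window (default 2000).
#' @param subpixel_nm histogram bin size (default 20 nm).
#' @param roi_mask `NULL`, or a predicate `function(x, y)` returning a
#'   logical to keep (e.g. a cortical annulus).
#' @param smooth_sigma_bins Gaussian smoothing of the histograms before
#'   correlation, in bins.
#' @param pairs `"successive"` (default) or `"all"` for the redundant
#'   least-squares variant.
#' @return drift tibble `frame`, `dx`, `dy` (nm); the first window is the
#'   reference with zero displacement.
#' @export
drift_rcc <- function(table, window_frames = 2000, subpixel_nm = 20,
                      roi_mask = NULL, smooth_sigma_bins = 2,
                      pairs = c("successive", "all")) {
  pairs <- match.arg(pairs)
  tbl <- table
  if (!is.null(roi_mask)) tbl <- dplyr::filter(tbl, roi_mask(.data$x, .data$y))
  f_min <- min(table$frame); f_max <- max(table$frame)
  n_frames <- f_max - f_min + 1
  n_win <- floor(n_frames / window_frames)
  abort_if(n_win < 2, "need at least two full windows for RCC")
  win_of <- pmin(floor((tbl$frame - f_min) / window_frames) + 1L, n_win)
  counts <- tabulate(win_of, nbins = n_win)
  # merge under-filled windows into their predecessor
  win_map <- seq_len(n_win)
  for (w in seq_len(n_win)) {
    if (counts[w] < 100 && n_win > 2) {
      rlang::warn(sprintf("window %d has %d localizations; merged with neighbor",
                          w, counts[w]))
      win_map[w] <- if (w > 1) win_map[w - 1] else 2L
    }
  }
  groups <- unique(win_map)
  extent <- c(min(tbl$x), max(tbl$x), min(tbl$y), max(tbl$y))
  hists <- purrr::map(groups, function(g) {
    sel <- win_map[win_of] == g
    h <- hist2d_counts(tbl$x[sel], tbl$y[sel], extent, subpixel_nm)
    if (smooth_sigma_bins > 0) h <- gaussian_blur(h, smooth_sigma_bins)
    h
  })
  mids <- purrr::map_dbl(groups, function(g) {
    w <- which(win_map == g)
    f_min + (min(w) - 1) * window_frames + (length(w) * window_frames - 1) / 2
  })
  m <- length(hists)
  if (pairs == "successive") {
    shifts <- purrr::map(seq_len(m - 1),
                         ~ xcorr_shift(hists[[.x]], hists[[.x + 1]]))
    cum <- rbind(c(0, 0), apply(do.call(rbind, shifts), 2, cumsum))
  } else {
    # redundant all-pairs least squares: every pair (i < j) measures
    # d_j - d_i; solve for window displacements with d_1 = 0
    rows <- list(); rhs <- list(); r <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      sh <- xcorr_shift(hists[[i]], hists[[j]])
      r <- r + 1
      a <- numeric(m - 1)
      if (j > 1) a[j - 1] <- 1
      if (i > 1) a[i - 1] <- a[i - 1] - 1
      rows[[r]] <- a; rhs[[r]] <- sh
    }
    A <- do.call(rbind, rows); Bm <- do.call(rbind, rhs)
    sol <- qr.solve(A, Bm)
    cum <- rbind(c(0, 0), sol)
  }
  cum <- cum * subpixel_nm
  frames <- seq(f_min, f_max)
  dx <- stats::spline(mids, cum[, 1], xout = frames, method = "natural")$y
  dy <- stats::spline(mids, cum[, 2], xout = frames, method = "natural")$y
  tibble::tibble(frame = frames, dx = dx, dy = dy)
}

#' Apply drift and chromatic corrections to a localization table
#'
#' Subtracts the per-frame drift from the coordinates, then (optionally)
#' applies a chromatic affine transform mapping this channel onto the
#' reference channel. Uncertainties are left unchanged.
#'
#' @param table localization tibble.
#' @param drift drift tibble (`frame`, `dx`, `dy`) covering all frames in
#'   `table`, or `NULL`.
#' @param affine an [affine2d()] mapping this channel onto the reference
#'   channel, or `NULL`.
#' @return corrected tibble of the same shape.
#' @export
apply_corrections <- function(table, drift = NULL, affine = NULL) {
  out <- table
  if (!is.null(drift)) {
    idx <- match(out$frame, drift$frame)
    abort_if(anyNA(idx), "drift trajectory does not cover all frames")
    out$x <- out$x - drift$dx[idx]
    out$y <- out$y - drift$dy[idx]
  }
  if (!is.null(affine)) {
    xy <- apply_affine(cbind(out$x, out$y), affine)
    out$x <- xy[, 1]; out$y <- xy[, 2]
  }
  out
}
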