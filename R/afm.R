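#' Extract the relaxed force plateau from an AFM compression curve
#'
#' After the compression peak the force relaxes over 20-30 s to a
#' plateau; the plateau force is the mean over the interval from the end
#' of the relaxation window to drug addition (or the end of the curve).
#' The residual slope over that interval is reported, and a slope above
#' `slope_tol_nN_per_s` flags the plateau as non-stationary.
#'
#' @param curve force-curve tibble (`time_s`, `force_nN`).
#' @param relax_window_s relaxation window after the peak, `c(min, max)`;
#'   the plateau starts at `t_peak + max`.
#' @param drug_time_s end of the plateau interval (`NA` = curve end).
#' @param slope_tol_nN_per_s stationarity tolerance.
#' @return list `plateau_nN`, `t_peak_s`, `slope_nN_per_s`, `stationary`,
#'   `no_peak` (TRUE when the curve has no identifiable compression
#'   peak, in which case the overall mean is returned with a warning).
#' @export
extract_plateau <- function(curve, relax_window_s = c(20, 30),
                            drug_time_s = NA, slope_tol_nN_per_s = 0.02) {
  t <- curve$time_s; f <- curve$force_nN
  abort_if(any(diff(t) <= 0), "time must be strictly increasing")
  k <- which.max(f)
  t_end <- if (is.na(drug_time_s)) max(t) else drug_time_s
  no_peak <- FALSE
  if (k == length(t) || max(f) - stats::median(f) <
      2 * stats::mad(diff(f)) + 1e-12) {
    # constant or monotone-rising curve: no compression peak
    no_peak <- TRUE
    rlang::warn("no compression peak identified; using the overall mean")
    sel <- t <= t_end
  } else {
    start <- t[k] + relax_window_s[2]
    abort_if(start >= t_end,
             "no samples between the relaxation window and the plateau end")
    sel <- t >= start & t <= t_end
  }
  abort_if(!any(sel), "empty plateau interval")
  slope <- if (sum(sel) > 2) unname(stats::coef(stats::lm(f[sel] ~ t[sel]))[2]) else 0
  list(plateau_nN = mean(f[sel]), t_peak_s = t[k],
       slope_nN_per_s = slope,
       stationary = abs(slope) <= slope_tol_nN_per_s,
       no_peak = no_peak)
}

#' Contact radius from the mid-plane area and cell height
#'
#' For a cell compressed between parallel plates, the cell-cantilever
#' contact area is computed from the maximum (equatorial) cross-sectional
#' area and the compressed cell height as
#' `A_c = A_mid - (pi/4) h_cell^2`, and the contact radius as
#' `r_c = sqrt(A_c / pi)`. (The relation is applied as an area balance;
#' see the methods vignette for the convention discussion.)
#'
#' @param A_mid_um2 maximum cross-sectional area (um^2).
#' @param h_cell_um compressed cell height (um).
#' @return contact radius r_c (um).
#' @export
contact_radius <- function(A_mid_um2, h_cell_um) {
  abort_if(h_cell_um < 0, "cell height must be >= 0")
  abort_if(A_mid_um2 <= (pi / 4) * h_cell_um^2,
           "A_mid must exceed (pi/4) h_cell^2 (cell taller than wide)")
  A_c <- A_mid_um2 - (pi / 4) * h_cell_um^2
  sqrt(A_c / pi)
}

#' Cortical tension from the force balance at the contact line
#'
#' `T = F (r_mid^2 / r_c^2 - 1) / (2 pi r_mid)`, with F in nN and radii
#' in um, giving T in nN/um = mN/m. Vanishes exactly when the contact
#' radius equals the mid-plane radius.
#'
#' @param F_nN plateau force (nN).
#' @param r_mid_um mid-plane radius (um).
#' @param r_c_um contact radius (um), `0 < r_c <= r_mid`.
#' @return cortical tension (mN/m).
#' @export
cortical_tension <- function(F_nN, r_mid_um, r_c_um) {
  abort_if(F_nN < 0, "force must be >= 0")
  abort_if(r_c_um <= 0 || r_c_um > r_mid_um,
           "need 0 < r_c <= r_mid")
  F_nN * (r_mid_um^2 / r_c_um^2 - 1) / (2 * pi * r_mid_um)
}

#' Compressed cell height from cantilever z positions
#'
#' @param z_on_cell_um cantilever z when compressing the cell (um).
#' @param z_on_glass_um cantilever z on the glass nearby (um).
#' @return cell height (um).
#' @export
measure_h_cell <- function(z_on_cell_um, z_on_glass_um) {
  h <- z_on_cell_um - z_on_glass_um
  abort_if(h < 0, "negative cell height; check the input order")
  h
}

#' End-to-end tension from a force curve and cell geometry
#'
#' Chains [extract_plateau()], [contact_radius()] and
#' [cortical_tension()].
#'
#' @param curve force-curve tibble.
#' @param A_mid_um2 mid-plane cross-sectional area (um^2).
#' @param h_cell_um compressed cell height (um).
#' @param ... passed to [extract_plateau()].
#' @return one-row tibble of class `tension_result`: `F_nN`, `r_mid_um`,
#'   `A_mid_um2`, `h_cell_um`, `r_c_um`, `tension_mN_per_m`.
#' @export
tension_from_curve <- function(curve, A_mid_um2, h_cell_um, ...) {
  pl <- extract_plateau(curve, ...)
  r_mid <- sqrt(A_mid_um2 / pi)
  r_c <- contact_radius(A_mid_um2, h_cell_um)
  out <- tibble::tibble(
    F_nN = pl$plateau_nN, r_mid_um = r_mid, A_mid_um2 = A_mid_um2,
    h_cell_um = h_cell_um, r_c_um = r_c,
    tension_mN_per_m = cortical_tension(pl$plateau_nN, r_mid, r_c),
    plateau_stationary = pl$stationary)
  class(out) <- c("tension_result", class(out))
  out
}

#' Normalized drug-response statistics of an AFM force curve
#'
#' The curve is smoothed with a Savitzky-Golay filter (polynomials up to
#' the filter order are reproduced exactly); the baseline is the mean
#' force over the `pre_window_s` seconds before drug addition, and the
#' outputs are mean(post)/baseline and max(post)/baseline over the
#' `post_window_s` seconds after it. A transient rise followed by decay
#' gives max ratio > 1 with mean ratio < 1 (low-dose signature); an
#' immediate monotone drop gives max ratio about 1 with mean ratio < 1
#' (high-dose signature).
#'
#' @param curve force-curve tibble.
#' @param t_drug_s drug addition time (s).
#' @param pre_window_s baseline window (default 20 s).
#' @param post_window_s response window (default 300 s).
#' @param sg_window,sg_order Savitzky-Golay length (odd) and order.
#' @return list `mean_ratio`, `max_ratio`, `baseline_nN`.
#' @export
drug_response <- function(curve, t_drug_s, pre_window_s = 20,
                          post_window_s = 300, sg_window = 21, sg_order = 3) {
  t <- curve$time_s
  abort_if(min(t) > t_drug_s - pre_window_s,
           sprintf("curve must cover %g s before drug addition", pre_window_s))
  abort_if(max(t) < t_drug_s + post_window_s,
           sprintf("curve must cover %g s after drug addition", post_window_s))
  sm <- signal::sgolayfilt(curve$force_nN, p = sg_order, n = sg_window)
  pre <- t >= t_drug_s - pre_window_s & t < t_drug_s
  post <- t >= t_drug_s & t <= t_drug_s + post_window_s
  baseline <- mean(sm[pre])
  abort_if(!is.finite(baseline) || baseline == 0, "undefined baseline force")
  list(mean_ratio = mean(sm[post]) / baseline,
       max_ratio = max(sm[post]) / baseline,
       baseline_nN = baseline)
}
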