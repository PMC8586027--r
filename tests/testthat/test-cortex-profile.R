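test_that("FWHM measurement matches closed forms and rejects bad profiles", {
  x <- seq(-500, 500, by = 5)
  # exact Gaussian, sigma 50 -> FWHM 2 sqrt(2 ln 2) * 50 = 117.74
  g <- measure_fwhm(x, exp(-x^2 / (2 * 50^2)))
  expect_true(g$ok)
  expect_lt(abs(g$fwhm_nm - 117.74), 0.5)
  expect_lt(abs(g$peak_nm), 2.5)
  # symmetric triangle of half-width 100 -> FWHM 100
  tri <- pmax(0, 1 - abs(x) / 100)
  t <- measure_fwhm(x, tri)
  expect_lt(abs(t$fwhm_nm - 100), 1)
  # monotone ramp has no interior peak
  r <- measure_fwhm(x, seq_along(x) / length(x))
  expect_false(r$ok)
  expect_equal(r$reason, "no_interior_peak")
  # truncated profile (no crossing on one side) is rejected with a reason
  half_gauss <- exp(-(x - 450)^2 / (2 * 80^2))
  tr <- measure_fwhm(x, half_gauss)
  expect_false(tr$ok)
})

test_that("overhang interval formula matches the rasterized oracle", {
  expect_equal(overhang_interval(-100, 100, -100, 100), 0)
  expect_equal(overhang_interval(-100, 100, -40, 180), 100 * 80 / 220,
               tolerance = 1e-12)
  expect_equal(overhang_interval(-100, 100, -120, 60), 100 * (-40) / 180,
               tolerance = 1e-12)
  for (case in list(c(-100, 100, -40, 180), c(-100, 100, -120, 60),
                    c(0, 200, 30, 250), c(-80, 120, -80, 120))) {
    expect_lt(abs(overhang_interval(case[1], case[2], case[3], case[4]) -
                    raster_overhang_oracle(case[1], case[2], case[3],
                                           case[4])), 0.5)
  }
  expect_error(overhang_interval(-100, 100, 50, 50), "degenerate")
  # symmetric two-sided non-overlap alternative
  expect_equal(nonoverlap_interval(-100, 100, -100, 100), 0)
  expect_equal(nonoverlap_interval(-100, 100, -40, 180),
               100 * 80 / 220, tolerance = 1e-12)
  expect_equal(nonoverlap_interval(-100, 100, -120, 60),
               100 * 20 / 180, tolerance = 1e-12)
})

test_that("overhang is invariant to rigid shifts and intensity rescaling", {
  x <- seq(-500, 500, by = 10)
  prof_a <- exp(-x^2 / (2 * 85^2))
  prof_t <- exp(-(x - 30)^2 / (2 * 95^2))
  ma <- measure_fwhm(x, prof_a); mt <- measure_fwhm(x, prof_t)
  ov0 <- overhang_interval(ma$fwhm_lo_nm, ma$fwhm_hi_nm,
                           mt$fwhm_lo_nm, mt$fwhm_hi_nm)
  # common rigid shift of both profiles
  ma2 <- measure_fwhm(x + 123, prof_a); mt2 <- measure_fwhm(x + 123, prof_t)
  ov1 <- overhang_interval(ma2$fwhm_lo_nm, ma2$fwhm_hi_nm,
                           mt2$fwhm_lo_nm, mt2$fwhm_hi_nm)
  expect_equal(ov1, ov0, tolerance = 1e-9)
  # per-channel intensity rescaling
  ma3 <- measure_fwhm(x, 7.3 * prof_a); mt3 <- measure_fwhm(x, 0.2 * prof_t)
  ov2 <- overhang_interval(ma3$fwhm_lo_nm, ma3$fwhm_hi_nm,
                           mt3$fwhm_lo_nm, mt3$fwhm_hi_nm)
  expect_equal(ov2, ov0, tolerance = 1e-9)
  # self-comparison is exactly zero, and so is the peak-to-peak distance
  expect_equal(overhang_interval(ma$fwhm_lo_nm, ma$fwhm_hi_nm,
                                 ma$fwhm_lo_nm, ma$fwhm_hi_nm), 0)
  expect_equal(peak_to_peak(ma, ma), 0)
  expect_gt(peak_to_peak(ma, mt), 0)
  # membrane-shifted target (moesin-like) gives a negative distance
  mt_mem <- measure_fwhm(x, exp(-(x + 40)^2 / (2 * 85^2)))
  expect_lt(peak_to_peak(ma, mt_mem), 0)
})

test_that("straightening a straight band is an identity up to interpolation", {
  tbl <- straight_band_table(seed = 2)
  img <- render_localizations(tbl, 10, extent = c(0, 6000, 0, 2000))
  seeds <- cbind(seq(1000, 5000, length.out = 24), rep(1000, 24))
  contour <- detect_cortex(img, seeds, cytoplasm_side = "left")
  st <- straighten(img, contour, half_width_nm = 400)
  bins <- bin_profiles(st, 200)
  meas <- measure_bins(bins)
  acc <- dplyr::filter(meas, .data$ok)
  expect_gt(nrow(acc), 10)
  # band centred on the contour (within a rendering pixel) and FWHM close
  # to the rendered width
  expect_lt(abs(mean(acc$peak_nm)), 10)
  rendered_fwhm <- sqrt(200^2 + (2.355 * 20)^2)
  expect_lt(abs(mean(acc$fwhm_nm) - rendered_fwhm), 10)
})

test_that("straightened profiles are invariant to scene rotation", {
  fwhm_for_angle <- function(theta) {
    tbl <- straight_band_table(seed = 3, x_range = c(-3000, 3000),
                               y_center = 0)
    rot <- tbl
    rot$x <- tbl$x * cos(theta) - tbl$y * sin(theta) + 4000
    rot$y <- tbl$x * sin(theta) + tbl$y * cos(theta) + 4000
    img <- render_localizations(rot, 10, extent = c(0, 8000, 0, 8000))
    s <- seq(-2500, 2500, length.out = 24)
    seeds <- cbind(4000 + s * cos(theta), 4000 + s * sin(theta))
    contour <- detect_cortex(img, seeds, cytoplasm_side = "left")
    st <- straighten(img, contour, half_width_nm = 400)
    meas <- dplyr::filter(measure_bins(bin_profiles(st, 200)), .data$ok)
    mean(meas$fwhm_nm)
  }
  f0 <- fwhm_for_angle(0)
  f30 <- fwhm_for_angle(30 * pi / 180)
  expect_lt(abs(f30 - f0), 5)
})

test_that("binning follows the 20-pixel rule and drops incomplete bins", {
  # synthetic straightened object: 50 rows of 10 nm pitch = 2.5 bins
  st <- structure(list(
    channels = list(ch1 = matrix(rep(exp(-seq(-300, 300, 10)^2 / (2 * 70^2)),
                                     each = 50), nrow = 50)),
    axis_nm = seq(-300, 300, 10),
    arc_nm = seq(0, by = 10, length.out = 50),
    complete = rep(TRUE, 50)), class = "straightened_cortex")
  bins <- bin_profiles(st, 200)
  expect_equal(max(bins$bin), 2)  # trailing half-bin dropped
  # uniform band: all bins identical
  expect_equal(bins$profile[[1]], bins$profile[[2]])
  # a bin containing flagged rows is excluded
  st$complete[25] <- FALSE
  bins2 <- bin_profiles(st, 200)
  expect_equal(unique(bins2$bin), 1)
})

test_that("per-cell aggregation averages accepted bins and enforces minimum", {
  tb <- tibble::tibble(bin = 1:5, arc_center_nm = (1:5) * 200,
                       accepted = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                       actin_fwhm_nm = 200, target_fwhm_nm = 220,
                       peak_to_peak_nm = 40, overhang_pct = 22)
  res <- aggregate_cell(tb)
  expect_equal(res$overhang_pct, 22)
  expect_equal(res$n_bins, 4)
  expect_equal(res$n_rejected, 1)
  expect_error(aggregate_cell(dplyr::slice(tb, 1:2)), "at least 3")
})

test_that("curvature broadening bound reproduces the printed worst case", {
  b <- curvature_broadening_bound(5000, 200)
  expect_equal(b / 2, 5000 - sqrt(5000^2 - 100^2), tolerance = 1e-12)
  expect_lt(abs(b / 2 - 1.0), 0.01)   # per-edge shift ~1 nm
  expect_lte(b, 2.001)                # total inflation at most ~2 nm
  expect_equal(curvature_broadening_bound(5000, 0), 0)
  # monotonically decreasing in the radius at fixed slab
  radii <- seq(3000, 20000, by = 500)
  vals <- purrr::map_dbl(radii, curvature_broadening_bound,
                         slab_thickness_nm = 200)
  expect_true(all(diff(vals) < 0))
  expect_error(curvature_broadening_bound(80, 200), "exceed")
})

test_that("rendering only widens the band, less so at lower uncertainty", {
  pooled_fwhm <- function(unc) {
    tbl <- straight_band_table(n = 60000, uncertainty = unc, seed = 4)
    img <- render_localizations(tbl, 10, extent = c(0, 6000, 0, 2000))
    # pool the full straight band: isolates the convolution broadening
    profile <- rowMeans(img[, 150:450])
    measure_fwhm((seq_len(nrow(img)) - 0.5) * 10, profile)$fwhm_nm
  }
  f20 <- pooled_fwhm(20)
  f5 <- pooled_fwhm(5)
  expect_gt(f20, 200)          # convolution widens
  expect_gt(f20, f5)           # excess shrinks with uncertainty
  expect_lt(abs(f20 - sqrt(200^2 + (2.355 * 20)^2)), 6)
  expect_lt(abs(f5 - 200), 6)
})

test_that("cortex detection recovers a circular ridge within one pixel", {
  g <- gen_smlm_cortex(small_cortex_scene(n = 40000), 5)
  img <- render_localizations(g$actin, 10, c(0, 8000, 0, 8000))
  contour <- detect_cortex(img, default_seed_poly())
  radii <- sqrt(rowSums(sweep(contour$points, 2, c(4000, 4000))^2))
  # ridge sits at cell_radius - actin offset = 2400 nm
  expect_lt(abs(mean(radii) - 2400), 10)
  # seed exactly on the ridge of a noise-free band stays put
  s_arc <- seq(0, 2 * pi, length.out = 12000)[-1]
  clean <- tibble::tibble(frame = 1L, x = 4000 + 2400 * cos(s_arc),
                          y = 4000 + 2400 * sin(s_arc), uncertainty = 20,
                          intensity = 1000, channel = 1L)
  img_clean <- render_localizations(clean, 10, c(0, 8000, 0, 8000))
  ridge_seed <- circle_seed(c(4000, 4000), 2400, 36)
  c2 <- detect_cortex(img_clean, ridge_seed)
  shifts <- sqrt(rowSums((c2$points - ridge_seed)^2))
  expect_lt(stats::median(shifts), 3)
  # seeds over a hole in the band are dropped with a warning
  hole <- dplyr::filter(g$actin, atan2(.data$y - 4000, .data$x - 4000) > 0.3 |
                          atan2(.data$y - 4000, .data$x - 4000) < 0)
  img_hole <- render_localizations(hole, 10, c(0, 8000, 0, 8000))
  expect_warning(detect_cortex(img_hole, default_seed_poly()), "dropped")
})
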