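test_that("rendering is unit-mass per molecule, linear, and scaled by 100", {
  one <- tibble::tibble(frame = 1L, x = 500, y = 500, uncertainty = 20,
                        intensity = 1000, channel = 1L)
  img <- render_localizations(one, 10, extent = c(0, 1000, 0, 1000))
  expect_lt(abs(sum(img) - 100), 0.1)
  # peak sits at the molecule position
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(50, 50))

  expect_warning(zero <- render_localizations(one[0, ], 10,
                                              extent = c(0, 1000, 0, 1000)),
                 "empty")
  expect_true(all(zero == 0))

  two <- dplyr::bind_rows(one, dplyr::mutate(one, x = 320, y = 700))
  img2 <- render_localizations(two, 10, extent = c(0, 1000, 0, 1000))
  imgb <- render_localizations(dplyr::mutate(one, x = 320, y = 700), 10,
                               extent = c(0, 1000, 0, 1000))
  expect_equal(img2, img + imgb - img * 0, tolerance = 1e-12,
               ignore_attr = FALSE)
})

test_that("chromatic affine fit is exact on noiseless beads", {
  set.seed(42)
  ref <- cbind(runif(12, 0, 8000), runif(12, 0, 8000))
  expect_equal(fit_chromatic_affine(ref, ref)$linear, diag(2),
               tolerance = 1e-9)
  th <- 0.1 * pi / 180
  lin <- 1.002 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tf_true <- affine2d(lin, c(30, -15))
  moving <- apply_affine(ref, tf_true)  # distorted channel
  tf_fit <- fit_chromatic_affine(ref, moving)
  back <- apply_affine(moving, tf_fit)
  expect_lt(max(abs(back - ref)), 1e-6)
  expect_lt(attr(tf_fit, "residual_rms_nm"), 1e-6)
  # invariant to bead relabelling
  ord <- sample(nrow(ref))
  tf_perm <- fit_chromatic_affine(ref[ord, ], moving[ord, ])
  expect_equal(tf_perm$linear, tf_fit$linear, tolerance = 1e-9)
  expect_equal(tf_perm$translation, tf_fit$translation, tolerance = 1e-6)
  # parameter errors shrink with bead count (Monte-Carlo, jittered beads):
  # judged by the recovered transform's action on a fixed test grid
  grid <- as.matrix(expand.grid(x = seq(0, 8000, 2000),
                                y = seq(0, 8000, 2000)))
  true_grid <- apply_affine(grid, invert_affine(tf_true))
  err_for_n <- function(n) {
    mean(purrr::map_dbl(1:20, function(i) {
      set.seed(i)
      pts <- cbind(runif(n, 0, 8000), runif(n, 0, 8000))
      mv <- apply_affine(pts, tf_true) + matrix(rnorm(2 * n, 0, 5), n)
      fit <- fit_chromatic_affine(pts, mv)
      sqrt(mean((apply_affine(grid, fit) - true_grid)^2))
    }))
  }
  expect_lt(err_for_n(40), err_for_n(5) / sqrt(40 / 5) * 2)
  expect_error(fit_chromatic_affine(ref[1:2, ], moving[1:2, ]), "3 matched")
  col <- cbind(1:5 * 100, 1:5 * 50)
  expect_error(fit_chromatic_affine(col, col), "collinear")
})

test_that("fiducial tracks recover injected drift and filter sparse beads", {
  n_frames <- 2000
  drift <- linear_drift(c(100, 0))(seq_len(n_frames), n_frames)
  set.seed(5)
  bead <- tibble::tibble(frame = seq_len(n_frames),
                         x = 2000 + drift[, 1] + rnorm(n_frames, 0, 5),
                         y = 3000 + drift[, 2] + rnorm(n_frames, 0, 5),
                         uncertainty = 5, intensity = 5000, channel = 1L)
  # stationary noiseless bead: constant track
  stat_bead <- dplyr::mutate(bead, x = 2000, y = 3000)
  tr0 <- track_fiducials(stat_bead, cbind(2000, 3000), 500)
  expect_true(all(tr0$x == 2000))
  # drifting bead: recovered slope within 5%
  tr <- track_fiducials(bead, cbind(2000, 3000), 500)
  slope <- unname(coef(lm(tr$x ~ tr$frame))[2])
  expect_lt(abs(slope - 100 / (n_frames - 1)) / (100 / (n_frames - 1)), 0.05)
  # bead absent in 60% of frames is dropped with a warning
  sparse <- bead[sort(sample(n_frames, round(0.4 * n_frames))), ]
  sparse$x <- sparse$x + 3000  # second bead elsewhere
  both <- dplyr::bind_rows(bead, sparse)
  expect_warning(tr2 <- track_fiducials(both, rbind(c(2000, 3000),
                                                    c(5000, 3000)), 500),
                 "dropped")
  expect_equal(unique(tr2$bead), 1)
})

test_that("bead drift averages tracks and smooths jitter", {
  frames <- 1:1000
  tracks <- dplyr::bind_rows(purrr::map(1:4, function(k) {
    set.seed(k)
    tibble::tibble(bead = k, frame = frames,
                   x = 1000 * k + rnorm(1000, 0, 10),
                   y = 500 + rnorm(1000, 0, 10))
  }))
  dr <- drift_from_beads(tracks, smooth_window = 50)
  # true drift is zero; averaging 4 beads over a 50-frame window
  expect_lt(sqrt(mean(dr$dx^2 + dr$dy^2)), 3 * 10 / sqrt(4 * 50) * 2)
  # two identical constant tracks give zero drift exactly
  const <- dplyr::bind_rows(
    tibble::tibble(bead = 1, frame = frames, x = 100, y = 200),
    tibble::tibble(bead = 2, frame = frames, x = 900, y = 400))
  dr0 <- drift_from_beads(const)
  expect_true(all(abs(dr0$dx) < 1e-12 & abs(dr0$dy) < 1e-12))
})

test_that("RCC recovers injected drift from window cross-correlation", {
  sc <- cortex_scene(cell_radius = 2500, n_frames = 20000,
                     actin_band = list(offset_nm = 100, fwhm_nm = 200,
                                       n = 60000),
                     drift_fn = linear_drift(c(100, 60)))
  g <- gen_smlm_cortex(sc, 1)
  dr <- drift_rcc(g$actin, window_frames = 2000, subpixel_nm = 20)
  tr <- g$truth$drift_nm[dr$frame, ]
  ex <- dr$dx - tr[, 1]; ex <- ex - mean(ex)
  ey <- dr$dy - tr[, 2]; ey <- ey - mean(ey)
  expect_lt(sqrt(mean(ex^2 + ey^2)), 10)
  # idempotence: drift re-estimated on the corrected table is sub-pixel
  corrected <- apply_corrections(g$actin, dr)
  dr2 <- drift_rcc(corrected, window_frames = 2000, subpixel_nm = 20)
  expect_lt(sqrt(mean(dr2$dx^2 + dr2$dy^2)), 20)
})

test_that("RCC flags zero drift below one sub-pixel and merges thin windows", {
  sc <- cortex_scene(cell_radius = 2500, n_frames = 8000,
                     actin_band = list(offset_nm = 100, fwhm_nm = 200,
                                       n = 30000))
  g <- gen_smlm_cortex(sc, 2)
  dr <- drift_rcc(g$actin, window_frames = 2000, subpixel_nm = 20)
  expect_lt(max(abs(c(dr$dx, dr$dy))), 20)
  # a nearly-empty window is merged with its neighbour, with a warning
  thin <- dplyr::filter(g$actin, .data$frame <= 4000 | .data$frame > 6000 |
                          dplyr::row_number() %% 97 == 0)
  expect_warning(drift_rcc(thin, window_frames = 2000), "merged")
})

test_that("corrections subtract drift, apply the affine, and invert cleanly", {
  g <- gen_smlm_cortex(small_cortex_scene(n = 2000), 6)
  zero_drift <- tibble::tibble(frame = 1:1000, dx = 0, dy = 0)
  expect_equal(apply_corrections(g$actin, zero_drift), g$actin)
  tf <- affine2d(matrix(c(1.001, 0, 0, 0.999), 2), c(25, -10))
  fwd <- apply_corrections(g$actin, NULL, tf)
  back <- apply_corrections(fwd, NULL, invert_affine(tf))
  expect_lt(max(abs(back$x - g$actin$x)), 1e-9)
  expect_lt(max(abs(back$y - g$actin$y)), 1e-9)
  short_drift <- tibble::tibble(frame = 1:10, dx = 0, dy = 0)
  expect_error(apply_corrections(g$actin, short_drift), "cover")
})

test_that("drift + affine correction restores the undistorted band centres", {
  tf <- affine2d(matrix(c(1.002, 0, 0, 1.002), 2), c(30, -15))
  sc <- cortex_scene(cell_radius = 2500, n_frames = 4000,
                     actin_band = list(offset_nm = 100, fwhm_nm = 200,
                                       n = 15000),
                     target_band = list(offset_nm = 100, fwhm_nm = 200,
                                        n = 15000),
                     drift_fn = linear_drift(c(80, -40)),
                     chromatic_affine = tf,
                     beads = rbind(c(1200, 1200), c(6800, 1500),
                                   c(4000, 7000)))
  g <- gen_smlm_cortex(sc, 9)
  tracks <- track_fiducials(g$actin, sc$beads, 500)
  dr <- drift_from_beads(tracks)
  beads_a <- dplyr::summarise(
    track_fiducials(apply_corrections(g$actin, dr), sc$beads, 500),
    x = mean(x), y = mean(y), .by = bead)
  beads_b <- dplyr::summarise(
    track_fiducials(apply_corrections(g$target, dr), sc$beads, 500),
    x = mean(x), y = mean(y), .by = bead)
  fit <- fit_chromatic_affine(as.matrix(beads_a[, c("x", "y")]),
                              as.matrix(beads_b[, c("x", "y")]))
  corr <- apply_corrections(g$target, dr, fit)
  # band-centre estimate: mean radial depth of localizations
  depth <- 2500 - sqrt((corr$x - 4000)^2 + (corr$y - 4000)^2)
  depth <- depth[abs(depth - 100) < 400]  # exclude bead localizations
  expect_lt(abs(mean(depth) - 100), 2 * 20 / sqrt(length(depth)) * 10)
})
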