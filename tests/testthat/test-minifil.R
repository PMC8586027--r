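test_that("background homogenization removes smooth fields, keeps spots", {
  const <- matrix(7, 96, 96)
  expect_lt(max(abs(homogenize_background(const, 48))), 1e-9)
  # spots over an injected smooth gradient: gradient removed, contrast kept
  spots <- render_spots(cbind(c(1200, 2400), c(1600, 2000)), c(500, 500),
                        96, 40, 60)
  gradient <- outer(seq(0, 3, length.out = 96), seq(0, 2, length.out = 96),
                    "+")
  out <- homogenize_background(spots + gradient, 48)
  flat_ref <- homogenize_background(spots, 48)
  peak_idx <- which(spots > 0.5 * max(spots))
  expect_lt(max(abs(out[peak_idx] - flat_ref[peak_idx])) /
              max(flat_ref[peak_idx]), 0.05)
  # approximately idempotent on a spot-only image
  again <- homogenize_background(flat_ref, 48)
  expect_lt(max(abs(again[peak_idx] - flat_ref[peak_idx])) /
              max(flat_ref[peak_idx]), 0.05)
})

test_that("Richardson-Lucy deconvolution sharpens without moving peaks", {
  flat <- matrix(3, 64, 64)
  expect_lt(max(abs(rl_deconvolve(flat, 2, 10) - flat)) / 3, 1e-6)
  # two PSF-blurred spots separated by 250 nm at sigma 110 nm:
  # peak-to-valley contrast strictly increases with iterations
  img <- render_spots(cbind(c(1155, 1405), c(1280, 1280)), c(1000, 1000),
                      64, 40, 110)
  contrast <- purrr::map_dbl(c(2, 8, 20), function(it) {
    d <- rl_deconvolve(img, 110 / 40, it)
    prof <- d[32, ]
    peaks <- max(prof)
    valley <- prof[32]
    peaks / max(valley, 1e-12)
  })
  expect_true(all(diff(contrast) > 0))
  # a delta image keeps its single maximum in place
  delta <- matrix(0, 33, 33); delta[17, 17] <- 1
  d <- rl_deconvolve(delta, 1.5, 10)
  expect_equal(unname(which(d == max(d), arr.ind = TRUE)[1, ]), c(17, 17))
})

test_that("noise thresholding kills background and isolated pixels", {
  set.seed(8)
  noise <- matrix(rnorm(128 * 128, 0, 1), 128)
  cleaned <- threshold_and_clean(noise, c(1, 40, 1, 40))
  expect_lt(mean(cleaned > 0), 0.002)
  # a bright spot at SNR 10 survives
  spot <- render_spots(cbind(2000, 2000), 8000, 128, 40, 80)
  with_spot <- threshold_and_clean(noise + spot, c(1, 40, 1, 40))
  expect_gt(max(with_spot), 5)
  # a single isolated hot pixel is removed
  hot <- matrix(0, 64, 64); hot[30, 30] <- 100
  hot <- hot + matrix(rnorm(64 * 64, 0, 0.5), 64)
  expect_equal(max(threshold_and_clean(hot, c(1, 20, 1, 20))[30, 30]), 0)
  expect_error(threshold_and_clean(noise, matrix(FALSE, 128, 128)), "empty")
})

test_that("peak detection matches a brute-force maxima scan", {
  # one symmetric spot: one peak within 0.2 px of its centre
  img <- render_spots(cbind(1283, 1642), 1000, 64, 40, 50)
  pk <- detect_peaks(img, 40)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$x_nm - 1283), 0.2 * 40)
  expect_lt(abs(pk$y_nm - 1642), 0.2 * 40)
  # two spots 6 px apart give two peaks
  img2 <- render_spots(cbind(c(1210, 1450), c(1210, 1210)), c(900, 1100),
                       64, 40, 50)
  expect_equal(nrow(detect_peaks(img2, 40)), 2)
  # brute-force scan oracle on a random cleaned image
  set.seed(21)
  rnd <- matrix(0, 40, 40)
  rnd[sample(1600, 60)] <- runif(60, 1, 10)
  found <- detect_peaks(rnd, 40, margin_px = 0)
  brute <- 0
  for (i in 2:39) for (j in 2:39) {
    nb <- rnd[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (rnd[i, j] > 0 && rnd[i, j] > max(nb[-5])) brute <- brute + 1
  }
  # centroid refinement may merge peaks within one pixel, never add any
  expect_lte(nrow(found), brute)
  expect_gt(nrow(found), 0.7 * brute)
  # a flat plateau has no strict 8-neighbour maximum
  plateau <- matrix(0, 20, 20); plateau[8:12, 8:12] <- 5
  expect_equal(nrow(detect_peaks(plateau, 40, margin_px = 0)), 0)
})

test_that("pairing equals brute-force enumeration and validates by tail", {
  # two heads 300 nm apart with the tail at the midpoint
  g <- tibble::tibble(x_nm = c(1000, 1300), y_nm = c(1000, 1000))
  r <- tibble::tibble(x_nm = 1150, y_nm = 1010)
  rec <- pair_minifilaments(g, r)
  expect_equal(nrow(rec), 1)
  expect_true(rec$validated)
  expect_equal(rec$projected_length_nm, 300)
  # heads 150 nm apart: below d_min, no candidate
  g2 <- tibble::tibble(x_nm = c(1000, 1150), y_nm = c(1000, 1000))
  expect_equal(nrow(pair_minifilaments(g2, r)), 0)
  # property: all-pairs rule equals exhaustive enumeration on random scenes
  for (s in 1:100) {
    set.seed(s)
    gg <- tibble::tibble(x_nm = runif(30, 0, 6000), y_nm = runif(30, 0, 6000))
    rr <- tibble::tibble(x_nm = runif(12, 0, 6000), y_nm = runif(12, 0, 6000))
    rec <- pair_minifilaments(gg, rr)
    val <- rec[rec$validated, ]
    brute <- 0
    for (i in 1:29) for (j in (i + 1):30) {
      d <- sqrt((gg$x_nm[i] - gg$x_nm[j])^2 + (gg$y_nm[i] - gg$y_nm[j])^2)
      if (d >= 200 && d <= 400) {
        mx <- (gg$x_nm[i] + gg$x_nm[j]) / 2
        my <- (gg$y_nm[i] + gg$y_nm[j]) / 2
        td <- sqrt((rr$x_nm - mx)^2 + (rr$y_nm - my)^2)
        if (any(td <= 50)) brute <- brute + 1
      }
    }
    expect_equal(nrow(val), brute)
  }
})

test_that("validated detections on synthetic SIM scenes are accurate", {
  stats <- purrr::map_dfr(1:5, function(s) {
    g <- gen_sim_minifilaments(minifil_scene(n_filaments = 25,
                                             margin_nm = 2000), s)
    recs <- detect_minifilaments(g$green, g$red, g$pixel_size_nm, 60,
                                 background_roi = border_roi(256),
                                 homogenize_radius_px = 128)
    val <- recs[recs$validated, ]
    d2 <- outer(val$center_x, g$truth$x_nm, "-")^2 +
      outer(val$center_y, g$truth$y_nm, "-")^2
    nn <- apply(d2, 1, which.min)
    hit <- sqrt(d2[cbind(seq_len(nrow(val)), nn)]) < 100
    tibble::tibble(
      precision = mean(hit),
      recall = length(unique(nn[hit])) / nrow(g$truth),
      len_err = mean(val$projected_length_nm[hit] -
                       g$truth$projected_length_nm[nn[hit]]))
  })
  expect_gte(mean(stats$precision), 0.9)
  expect_gte(mean(stats$recall), 0.9)
  expect_lt(abs(mean(stats$len_err)), 10)
})

test_that("projected-length statistics follow the cosine model", {
  recs <- tibble::tibble(projected_length_nm = rep(300, 12),
                         validated = TRUE)
  st <- projected_length_stats(recs)
  expect_equal(st$mean_projected_nm, 300)
  expect_equal(st$sd_projected_nm, 0)
  expect_false(st$low_count)
  # theta uniform in [0, 30]: mean projection 317 * sin(30 deg)/(pi/6)
  g <- gen_sim_minifilaments(minifil_scene(n_filaments = 5000,
                                           theta_max_deg = 30,
                                           image_size_px = 1500), 2)
  truth_recs <- tibble::tibble(projected_length_nm =
                                 g$truth$projected_length_nm,
                               validated = TRUE)
  st2 <- projected_length_stats(truth_recs)
  e_len <- 317 * sin(pi / 6) / (pi / 6)
  expect_lt(abs(st2$mean_projected_nm - e_len),
            3 * st2$sd_projected_nm / sqrt(st2$n))
  expect_error(projected_length_stats(recs[0, ]), "no validated")
})

test_that("angle and tension follow the arccos / cosine-ratio model", {
  expect_equal(angle_from_projection(317, 317), 0)
  expect_equal(angle_from_projection(305, 317), acos(305 / 317) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(angle_from_projection(295, 317), acos(295 / 317) * 180 / pi,
               tolerance = 1e-12)
  expect_lt(abs(angle_from_projection(305, 317) - 15.8), 0.1)
  expect_lt(abs(angle_from_projection(295, 317) - 21.5), 0.1)
  expect_error(angle_from_projection(320, 317), "exceeds")
  # round trip: angle -> projection -> angle is the identity
  th <- seq(0, 89.9, by = 0.37)
  back <- angle_from_projection(317 * cos(th * pi / 180), 317)
  expect_lt(max(abs(back - th)), 1e-9)
  expect_equal(tension_change_from_angles(15, 15), 0)
  # interphase (21.5 deg) -> mitosis (15.8 deg): +3.4%, below 5%
  delta <- tension_change_from_angles(angle_from_projection(295, 317),
                                      angle_from_projection(305, 317))
  expect_equal(delta, 100 * (305 / 295 - 1), tolerance = 1e-9)
  expect_lt(delta, 5)
  # opening the angle reduces tension
  expect_lt(tension_change_from_angles(10, 30), 0)
})
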