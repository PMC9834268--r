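test_that("anchors are detected within 2 px on noiseless and noisy renders", {
  layout <- tiny_layout(12)
  cb <- default_codebook()
  for (optics in list(noiseless_optics(), optics_model())) {
    sim <- simulate_screen(layout, cb, timepoints_h = 48,
                           growth = tiny_growth(), seed = 17,
                           optics = optics)
    det <- detect_anchors(sim$frames[[1]], layout)
    expect_true(all(det$detected))
    gt_x <- layout$anchors$x_um / 10 - 0.5
    gt_y <- layout$anchors$y_um / 10 - 0.5
    err <- sqrt((det$x_px - gt_x)^2 + (det$y_px - gt_y)^2)
    expect_lt(max(err), 2)
  }
})

test_that("blank or structureless images raise a detection-failure error", {
  layout <- tiny_layout(6)
  blank <- chip_frame(list(bf = matrix(100, 200, 400)), 10)
  expect_error(detect_anchors(blank, layout), "detection failure.*0 of 6")
  set.seed(1)
  noise <- chip_frame(list(bf = matrix(rnorm(200 * 400, 100, 5), 200, 400)), 10)
  expect_error(detect_anchors(noise, layout), "detection failure")
})

test_that("a translated render yields centres shifted by the known offset", {
  layout <- tiny_layout(12)
  cb <- default_codebook()
  shift <- c(dx = 70, dy = -40)  # um
  shifted <- layout
  shifted$anchors$x_um <- shifted$anchors$x_um + shift[["dx"]]
  shifted$anchors$y_um <- shifted$anchors$y_um + shift[["dy"]]
  truth <- sim_truth <- simulate_screen(layout, cb, timepoints_h = 48,
                                        growth = tiny_growth(), seed = 17,
                                        optics = NULL)$truth
  optics <- optics_model()
  f0 <- render_chip_image(layout, truth, optics, seed = 4)
  f1 <- render_chip_image(shifted, truth, optics, seed = 4)
  d0 <- detect_anchors(f0$channels$bf, pixel_size_um = 10,
                       anchor_radius_um = layout$anchor_radius,
                       min_separation_px = 30)
  d1 <- detect_anchors(f1$channels$bf, pixel_size_um = 10,
                       anchor_radius_um = layout$anchor_radius,
                       min_separation_px = 30)
  expect_equal(nrow(d0), 12)
  expect_equal(nrow(d1), 12)
  expect_lt(max(abs(d1$x_px - d0$x_px - shift[["dx"]] / 10)), 2)
  expect_lt(max(abs(d1$y_px - d0$y_px - shift[["dy"]] / 10)), 2)

  # with a layout prior, the rigid lattice fit absorbs the translation
  det_fit <- detect_anchors(f1, layout)
  err <- sqrt((det_fit$x_um - shifted$anchors$x_um)^2 +
                (det_fit$y_um - shifted$anchors$y_um)^2) / 10
  expect_lt(max(err), 2)
})

test_that("disc segmentation recovers the diameter within 5%", {
  layout <- build_hexagonal_layout(3, chamber_area_mm2 = 8, pitch_um = 800,
                                   pixel_size_um = 10)
  cb <- default_codebook()
  truth <- truth_row(layout, cb, "dmso_a", diameter_um = 200)
  fr <- render_chip_image(layout, truth, noiseless_optics(), seed = 1)
  a <- layout$anchors[1, ]
  cr <- dropscreen:::crop_anchor(fr, a$x_um, a$y_um, 16, channels = "bf")
  roi <- dropscreen:::crop_roi_disc(dim(cr$channels$bf), cr$origin_px,
                                    a$x_um, a$y_um, 160, 10)
  sph <- segment_spheroid(cr$channels$bf, 10, anchor_id = 1L, roi = roi)
  expect_s3_class(sph, "spheroid_mask")
  expect_lt(abs(sph$equivalent_diameter_um / 200 - 1), 0.05)
  expect_gt(sph$circularity, 0.9)

  # the chip-level path agrees
  meas <- score_chip(fr, layout)
  expect_lt(abs(meas$diameter_um[1] / 200 - 1), 0.05)
})

test_that("empty droplets give NULL and the largest object wins", {
  set.seed(8)
  empty <- matrix(rnorm(41 * 41, 30000, 6), 41, 41)
  expect_null(segment_spheroid(empty, 10))

  crop <- matrix(30000, 41, 41)
  big <- dropscreen:::disc_pixels(41, 41, 200, 200, 80, 10)
  tiny <- dropscreen:::disc_pixels(41, 41, 60, 60, 15, 10)
  crop[big$idx] <- 12000
  crop[tiny$idx] <- 12000
  sph <- segment_spheroid(crop, 10)
  expect_equal(sph$area_px, length(big$idx))
  # centroid sits on the big disc, not the tiny one
  expect_gt(sph$centroid_px[["x"]], 10)
})

test_that("morphological selection rejects out-of-bounds and elongated objects", {
  crop <- matrix(30000, 41, 41)
  crop[dropscreen:::disc_pixels(41, 41, 200, 200, 25, 10)$idx] <- 12000
  expect_null(segment_spheroid(crop, 10,
                               segmentation_params(min_area_um2 = 5000)))
  bar <- matrix(30000, 41, 41)
  bar[19:23, 3:39] <- 12000  # 5 x 37 px bar: circularity ~ 0.5
  expect_null(segment_spheroid(bar, 10))
  expect_s3_class(segment_spheroid(bar, 10,
                                   segmentation_params(min_circularity = 0.2)),
                  "spheroid_mask")
})

test_that("local background threshold follows median + k * MAD", {
  mask <- matrix(FALSE, 41, 41)
  mask[dropscreen:::disc_pixels(41, 41, 200, 200, 60, 10)$idx] <- TRUE
  flat <- matrix(500, 41, 41)
  expect_equal(local_background_threshold(flat, mask, k = 3), 500)

  # Monte-Carlo oracle for Gaussian background
  set.seed(31)
  sigma <- 20
  thr <- replicate(40, {
    crop <- matrix(rnorm(41 * 41, 500, sigma), 41, 41)
    local_background_threshold(crop, mask, k = 3)
  })
  expect_lt(abs(mean(thr) - (500 + 3 * sigma)) / (500 + 3 * sigma), 0.05)

  full <- matrix(TRUE, 41, 41)
  expect_error(local_background_threshold(flat, full), "insufficient background")
})

test_that("viability scoring partitions pixels and honours the threshold", {
  mask <- matrix(FALSE, 41, 41)
  mask[dropscreen:::disc_pixels(41, 41, 200, 200, 60, 10)$idx] <- TRUE
  area <- sum(mask)
  crop <- matrix(100, 41, 41)
  m <- score_viability(crop, mask, threshold = 150)
  expect_equal(m$viability, 1)
  expect_equal(m$dead_pixel_count, 0)

  m0 <- score_viability(crop, mask, threshold = -Inf)
  expect_equal(m0$viability, 0)
  expect_equal(m0$dead_pixel_count, area)

  set.seed(5)
  dead_idx <- sample(which(mask), 40)
  crop[dead_idx] <- 4000
  m2 <- score_viability(crop, mask, threshold = 1000)
  expect_equal(m2$dead_pixel_count, 40)
  expect_equal(m2$dead_pixel_count + (area - m2$dead_pixel_count), m2$area_px)
  expect_equal(m2$viability + m2$dead_fraction, 1)
  expect_equal(m2$mean_dead_intensity, mean(crop[mask]))

  # CFSE exclusion removes flagged pixels from the mask
  excl <- matrix(FALSE, 41, 41)
  excl[dead_idx[1:10]] <- TRUE
  m3 <- score_viability(crop, mask, threshold = 1000, exclude = excl)
  expect_equal(m3$dead_pixel_count, 30)
  expect_equal(m3$area_px, area - 10)
})

test_that("dead fraction is non-increasing in the threshold multiplier k", {
  layout <- tiny_layout(6)
  cb <- default_codebook()
  truth <- do.call(rbind, lapply(1:6, function(i) {
    truth_row(layout, cb, "dmso_a", diameter_um = 120,
              dead_fraction = 0.3, anchor_id = i)
  }))
  fr <- render_chip_image(layout, truth, optics_model(), seed = 14)
  fracs <- vapply(c(0, 1, 3, 8), function(k) {
    mean(score_chip(fr, layout, k = k)$dead_fraction, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("noiseless scoring matches the pixel-count oracle exactly", {
  layout <- tiny_layout(3)
  cb <- default_codebook()
  truth <- truth_row(layout, cb, "dmso_b", diameter_um = 150,
                     dead_fraction = 0.30)
  fr <- render_chip_image(layout, truth, noiseless_optics(), seed = 3)
  meas <- score_chip(fr, layout)
  m1 <- meas[meas$anchor_id == 1, ]
  # oracle: the true digital disc
  sph <- dropscreen:::disc_pixels(nrow(fr$channels$pi), ncol(fr$channels$pi),
                                  layout$anchors$x_um[1],
                                  layout$anchors$y_um[1], 75, 10)
  expect_equal(m1$area_px, length(sph$idx))
  expect_equal(m1$dead_fraction,
               round(0.30 * length(sph$idx)) / length(sph$idx))
})

test_that("equivalent diameter follows the circle closed form and scaling law", {
  disc <- matrix(FALSE, 25, 25)
  disc[dropscreen:::disc_pixels(25, 25, 125, 125, 100, 10)$idx] <- TRUE
  d <- measure_diameter(disc, pixel_size_um = 1)
  expect_lt(abs(d - 20), 1)  # radius 10 px -> 20 um at 1 um/px, +- 1 px
  expect_equal(measure_diameter(400, 1) / measure_diameter(100, 1), 2)
  expect_equal(measure_diameter(100, 2), measure_diameter(100, 1) * 2)
})

test_that("a rendered growth series reproduces the logistic trajectory", {
  layout <- build_hexagonal_layout(12, chamber_area_mm2 = 8, pitch_um = 500,
                                   pixel_size_um = 5)
  cb <- default_codebook()
  g <- growth_spec(d0_um = 80, dmax_um = 150, sdlog = 0)
  sim <- simulate_screen(layout, cb, timepoints_h = c(0, 24, 72, 144),
                         growth = g, seed = 6, noise_phi = Inf)
  for (fr in sim$frames) {
    truth <- sim$truth[sim$truth$timepoint_h == fr$timepoint, ]
    meas <- score_chip(fr, layout)
    ok <- meas$qc_flags == ""
    expect_true(all(ok))
    expect_lt(max(abs(meas$diameter_um[ok] / truth$true_diameter_um[ok] - 1)),
              0.05)
  }
})
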