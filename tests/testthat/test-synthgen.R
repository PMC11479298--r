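test_that("sensor image spec validates geometry and derives physical area", {
  spec <- sensor_image_spec(2000, 2000)
  expect_equal(imaged_area_cm2(spec), 0.04)
  # a full 6 cm frame at 1 px/um would be 60,000 px across
  expect_equal(spec$frame_size_cm * spec$resolution_px_per_um * 1e4, 60000)
  expect_error(sensor_image_spec(8, 100), "at least 16")
  expect_error(sensor_image_spec(100, 100, resolution_px_per_um = 0),
               "positive")
  expect_error(sensor_image_spec(100, 100, background_mean = 100),
               "white paper")
})

test_that("sample_particles draws the requested count within class strata", {
  spec <- sensor_image_spec(1000, 1000)
  expect_equal(nrow(sample_particles(spec, 0, seed = 7)), 0)

  gt <- sample_particles(spec, 100, mixture = pm10_mixture,
                         min_gap_px = 2, seed = 1)
  expect_equal(nrow(gt), 100)
  expect_true(all(gt$diameter_um > 2.5 & gt$diameter_um <= 10))
  # exhaustive pairwise edge-to-edge separation check
  dmat <- as.matrix(dist(cbind(gt$center_x_px, gt$center_y_px)))
  rsum <- outer(gt$diameter_um / 2, gt$diameter_um / 2, `+`)
  gaps <- dmat - rsum
  diag(gaps) <- Inf
  expect_true(all(gaps >= 2))

  mixed <- sample_particles(spec, 300, seed = 3)
  expect_true(all(mixed$diameter_um > 0 & mixed$diameter_um <= 10))
  expect_true(all(mixed$grey_level >= 0 & mixed$grey_level <= 120))
  strata <- list(PM1 = c(0, 1), PM2_5 = c(1, 2.5), PM10 = c(2.5, 10))
  for (cls in names(strata)) {
    d <- mixed$diameter_um[mixed$pm_class == cls]
    expect_true(all(d > strata[[cls]][1] & d <= strata[[cls]][2]))
  }
})

test_that("infeasible densities raise a placement error, bad mixtures too", {
  spec <- sensor_image_spec(100, 100)
  expect_error(
    sample_particles(spec, 1e6, min_gap_px = 2, seed = 1,
                     max_attempts = 1e5),
    "infeasible")
  expect_error(sample_particles(spec, 10, mixture = c(PM1 = -1, PM2_5 = 1,
                                                      PM10 = 1), seed = 1),
               "invalid mixture")
  expect_error(sample_particles(spec, 10, mixture = c(PM1 = 0, PM2_5 = 0,
                                                      PM10 = 0), seed = 1),
               "invalid mixture")
})

test_that("rendering an empty scene gives a constant background", {
  spec <- sensor_image_spec(64, 64, background_sigma = 0)
  out <- render_sensor_image(spec, sample_particles(spec, 0, seed = 1),
                             seed = 1)
  expect_equal(dim(out$image), c(64, 64, 3))
  expect_true(all(out$image == 245))
  expect_equal(out$truth$n_total, 0)
})

test_that("a rendered disk has the analytic pixel area", {
  # 10 um disk at 1 px/um: pi * 5^2 ~ 78.5 px when counted below mid-grey
  spec <- sensor_image_spec(64, 64, background_sigma = 0)
  p <- data.frame(id = 1L, center_x_px = 32.2, center_y_px = 31.7,
                  diameter_um = 10, grey_level = 0,
                  pm_class = factor("PM10", levels = levels(pm_class(1))))
  img <- render_sensor_image(spec, p, seed = 1)$image
  measured <- sum(img[, , 1] < (245 + 0) / 2)
  expect_lt(abs(measured - pi * 25), 1 + 1e-8)
})

test_that("rendered disk areas match pi r^2 within max(2, 10%) px", {
  # rendered area via coverage unmixing: each pixel's darkening relative to
  # the background is its disk-coverage fraction, so the summed darkening is
  # the rendered area in px^2
  spec <- sensor_image_spec(400, 400, background_sigma = 0)
  gt <- sample_particles(spec, 20, mixture = pm10_mixture, min_gap_px = 5,
                         seed = 9)
  gt$grey_level <- 0L
  img <- render_sensor_image(spec, gt, seed = 9)$image[, , 1]
  for (k in seq_len(20)) {
    r <- gt$diameter_um[k] / 2
    rows <- pmax(1, floor(gt$center_y_px[k] - r - 2)):
      pmin(400, ceiling(gt$center_y_px[k] + r + 2))
    cols <- pmax(1, floor(gt$center_x_px[k] - r - 2)):
      pmin(400, ceiling(gt$center_x_px[k] + r + 2))
    measured <- sum((245 - img[rows, cols]) / 245)
    expected <- pi * r^2
    expect_lt(abs(measured - expected), max(2, 0.1 * expected))
  }
})

test_that("generation is bit-reproducible for a fixed seed", {
  spec <- sensor_image_spec(200, 200)
  a <- render_sensor_image(spec, sample_particles(spec, 30, seed = 5),
                           seed = 6)
  b <- render_sensor_image(spec, sample_particles(spec, 30, seed = 5),
                           seed = 6)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$particles, b$truth$particles)
  c <- render_sensor_image(spec, sample_particles(spec, 30, seed = 5),
                           seed = 7)
  expect_false(identical(a$image, c$image))
})

test_that("out-of-bounds particles are rejected at render time", {
  spec <- sensor_image_spec(64, 64)
  p <- data.frame(id = 1L, center_x_px = 99, center_y_px = 10,
                  diameter_um = 5, grey_level = 0,
                  pm_class = factor("PM10", levels = levels(pm_class(1))))
  expect_error(render_sensor_image(spec, p, seed = 1), "out of image bounds")
})

test_that("generate_dataset writes one image/truth pair per cell plus manifest", {
  out_dir <- withr::local_tempdir()
  spec <- sensor_image_spec(64, 64)
  grid <- list(
    list(spec = spec, n = 3, seed = 1),
    list(spec = spec, n = 5, seed = 2,
         degradation = degradation_config(gaussian = list(mean = 2,
                                                          variance = 4),
                                          seed = 2)),
    list(spec = spec, n = 0, seed = 3))
  manifest <- generate_dataset(grid, out_dir)
  expect_equal(nrow(manifest), 3)
  expect_true(all(file.exists(manifest$image_path)))
  expect_true(all(file.exists(manifest$truth_path)))
  expect_equal(manifest$gaussian_mean, c(NA, 2, NA))

  # determinism: re-running leaves every file byte-identical
  md5_before <- tools::md5sum(list.files(out_dir, full.names = TRUE))
  generate_dataset(grid, out_dir)
  md5_after <- tools::md5sum(list.files(out_dir, full.names = TRUE))
  expect_identical(md5_before, md5_after)

  # empty grid: empty manifest, no image/truth files
  empty_dir <- withr::local_tempdir()
  m2 <- generate_dataset(list(), empty_dir)
  expect_equal(nrow(m2), 0)
  expect_equal(list.files(empty_dir), "manifest.csv")

  # ground truth survives a JSON round trip
  tr <- read_ground_truth(manifest$truth_path[2])
  expect_equal(tr$n_total, 5)
  expect_equal(sum(tr$n_by_class), 5)
})
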