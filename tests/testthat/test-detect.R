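test_that("grayscale conversion uses Rec. 601 luma weights", {
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  expect_equal(as.numeric(to_grayscale(px(100, 100, 100))), 100)
  expect_equal(as.numeric(to_grayscale(px(255, 0, 0))), 76)
  white <- array(255, dim = c(5, 5, 3))
  expect_true(all(to_grayscale(white) == 255))
  expect_error(to_grayscale(matrix(1, 4, 4)), "3-channel")
})

test_that("bicubic upscaling reproduces constants and is identity at factor 1", {
  const <- matrix(200, 8, 8)
  up <- bicubic_upscale(const, 2.5)
  expect_equal(dim(up), c(20, 20))
  expect_equal(up, matrix(200, 20, 20), tolerance = 1e-12)
  set.seed(5)
  m <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(bicubic_upscale(m, 1), m, tolerance = 1e-12)
  expect_error(bicubic_upscale(m, 0), "positive")
})

test_that("bicubic upscaling equals the brute-force 16-neighbour oracle", {
  set.seed(6)
  cases <- list(
    list(img = matrix(runif(64, 0, 255), 8, 8), factor = 2),
    list(img = outer(1:8, 1:8, `+`) * 10, factor = 2),          # ramp
    list(img = matrix(runif(12 * 16, 0, 255), 12, 16), factor = 1.6),
    list(img = matrix(runif(25, 0, 255), 5, 5), factor = 3.2)
  )
  for (cs in cases) {
    out_h <- round(cs$factor * nrow(cs$img))
    out_w <- round(cs$factor * ncol(cs$img))
    got <- bicubic_upscale(cs$img, cs$factor)
    want <- bicubic_oracle(cs$img, out_h, out_w)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # non-default kernel parameter
  img <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(bicubic_upscale(img, 2, a = -0.75),
               bicubic_oracle(img, 16, 16, a = -0.75), tolerance = 1e-6)
})

test_that("adaptive threshold implements the dark-on-light local-mean rule", {
  const <- matrix(180, 30, 30)
  expect_true(all(adaptive_threshold(const, 15, 5) == 0L))
  # all-dark image: nothing below its own local mean minus a positive offset
  expect_true(all(adaptive_threshold(matrix(0, 30, 30), 15, 10) == 0L))
  expect_error(adaptive_threshold(const, 14, 5), "odd")

  toy <- matrix(255, 31, 31)
  toy[16, 16] <- 0
  bin <- adaptive_threshold(toy, 15, 10)
  # direct windowed-mean oracle on the toy array
  want <- matrix(as.integer(toy < window_mean_oracle(toy, 15) - 10), 31, 31)
  expect_identical(bin, want)
  expect_equal(sum(bin), 1)
  expect_equal(which(bin == 1L), (16 - 1) * 31 + 16)
})

test_that("local mean matches the windowed oracle on random images", {
  set.seed(7)
  m <- matrix(runif(18 * 13, 0, 255), 18, 13)
  for (block in c(3, 7, 11)) {
    expect_equal(dustscan:::box_mean_cpp(m, as.integer(block)),
                 window_mean_oracle(m, block), tolerance = 1e-9)
  }
})

test_that("extract_particles labels 8-connected components and sizes them", {
  empty <- matrix(0L, 20, 20)
  expect_equal(nrow(extract_particles(empty)), 0)

  # a 78-px blob: equivalent circular diameter 2*sqrt(78/pi) ~ 9.97 -> PM10
  blob <- matrix(0L, 30, 30)
  blob[cbind(rep(5:13, each = 9), rep(5:13, times = 9))[1:78, ]] <- 1L
  got <- extract_particles(blob, working_resolution = 1)
  expect_equal(nrow(got), 1)
  expect_equal(got$area_px, 78)
  expect_equal(got$equiv_diameter_um, 2 * sqrt(78 / pi))
  expect_equal(as.character(got$pm_class), "PM10")

  # corner-touching pixels merge under 8-connectivity
  corners <- matrix(0L, 10, 10)
  corners[3, 3] <- 1L
  corners[4, 4] <- 1L
  expect_equal(nrow(extract_particles(corners, min_area_px = 0.5)), 1)
  # ... but diagonal-separated ones do not
  corners[4, 4] <- 0L
  corners[5, 5] <- 1L
  expect_equal(nrow(extract_particles(corners, min_area_px = 0.5)), 2)

  # min-area filter
  two <- matrix(0L, 20, 20)
  two[5, 5] <- 1L
  two[10:12, 10:12] <- 1L
  expect_equal(nrow(extract_particles(two, min_area_px = 2)), 1)
})

test_that("detect recovers the exact count on clean synthetic images", {
  scene <- make_scene(100, seed = 13, side = 1000)
  res <- detect_particles(scene$image,
                          calibration = calibration_from_spec(scene$spec))
  expect_equal(res$n_total, 100)
  expect_equal(res$n_pm10, 100)
  expect_equal(res$dots_per_cm2, 100 / imaged_area_cm2(scene$spec))

  blank <- render_sensor_image(sensor_image_spec(300, 300),
                               sample_particles(sensor_image_spec(300, 300),
                                                0, seed = 1), seed = 1)
  res0 <- detect_particles(blank$image,
                           calibration = calibration_info(px_per_cm = 1e4))
  expect_equal(res0$n_total, 0)

  # determinism: identical result on a rerun
  res2 <- detect_particles(scene$image,
                           calibration = calibration_from_spec(scene$spec))
  expect_identical(res, res2)

  expect_error(detect_particles(scene$image), "calibration")
})

test_that("clean-image count recovery holds for >= 99% of seeds", {
  # study-condition generator output (non-touching, diameters >= 2.5 um) at
  # the study density of ~25 particles per mm^2
  hits <- vapply(1:100, function(s) {
    scene <- make_scene(10, seed = s, side = 632)
    res <- detect_particles(scene$image,
                            calibration = calibration_from_spec(scene$spec))
    res$n_total == 10
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("equivalent diameters track ground truth within 1 um for d >= 3 um", {
  cal <- calibration_info(px_per_cm = 1e4)
  for (d in c(3, 4.5, 6, 8, 10)) {
    for (g in c(0, 60, 120)) {
      spec <- sensor_image_spec(80, 80, background_sigma = 0)
      p <- data.frame(id = 1L, center_x_px = 40.3, center_y_px = 39.6,
                      diameter_um = d, grey_level = g,
                      pm_class = factor("PM10", levels = levels(pm_class(1))))
      img <- render_sensor_image(spec, p, seed = 1)$image
      res <- detect_particles(img, calibration = cal)
      expect_equal(res$n_total, 1)
      expect_lt(abs(res$particles$equiv_diameter_um - d), 1)
    }
  }
})

test_that("low-resolution input is upscaled to the working resolution", {
  # native 0.5 px/um -> factor-2 bicubic upscale to 1 px/um
  spec <- sensor_image_spec(400, 400, resolution_px_per_um = 0.5,
                            background_sigma = 0)
  parts <- sample_particles(spec, 20, mixture = pm10_mixture,
                            min_gap_px = 4, seed = 3)
  keep <- parts$diameter_um >= 5  # resolvable at the coarse native scale
  parts <- parts[keep, ]
  img <- render_sensor_image(spec, parts, seed = 3)$image
  res <- detect_particles(img, calibration = calibration_from_spec(spec))
  expect_equal(res$working_resolution_px_per_um, 1)
  expect_equal(res$n_total, nrow(parts))
  expect_equal(res$area_cm2, imaged_area_cm2(spec))
})

test_that("median accuracy is non-increasing in blur strength", {
  strengths <- c(1, 2, 3, 4)
  acc <- matrix(NA_real_, nrow = 20, ncol = length(strengths))
  for (s in 1:20) {
    scene <- make_scene(40, seed = 100 + s, side = 500)
    for (k in seq_along(strengths)) {
      img <- apply_focus_blur(scene$image, 70, strengths[k])
      res <- detect_particles(img,
                              calibration = calibration_from_spec(scene$spec))
      acc[s, k] <- accuracy(res$n_total, 40)
    }
  }
  med <- apply(acc, 2, median)
  expect_true(all(diff(med) <= 0))
  # harshest blur must actually bite relative to clean
  expect_lt(med[length(strengths)], 100)
})
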