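# Independent brute-force oracles used to pin down the compiled kernels.
# These deliberately share no code with the package internals: plain R loops
# over the textbook definitions.

# cubic-convolution weight for offset s and kernel parameter a
cubic_weight <- function(s, a) {
  s <- abs(s)
  if (s <= 1) return((a + 2) * s^3 - (a + 3) * s^2 + 1)
  if (s < 2) return(a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a)
  0
}

# direct 16-neighbour bicubic resampling: per-output-pixel double loop over
# the 4x4 stencil, centre-aligned mapping, replicated borders
bicubic_oracle <- function(img, out_h, out_w, a = -0.5) {
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(0, out_h, out_w)
  for (oi in seq_len(out_h)) {
    y <- (oi - 0.5) * h / out_h - 0.5
    iy <- floor(y)
    ty <- y - iy
    for (oj in seq_len(out_w)) {
      x <- (oj - 0.5) * w / out_w - 0.5
      ix <- floor(x)
      tx <- x - ix
      acc <- 0
      for (t in 0:3) {
        si <- min(h - 1, max(0, iy + t - 1))
        for (u in 0:3) {
          sj <- min(w - 1, max(0, ix + u - 1))
          acc <- acc + cubic_weight(ty - (t - 1), a) *
            cubic_weight(tx - (u - 1), a) * img[si + 1, sj + 1]
        }
      }
      out[oi, oj] <- acc
    }
  }
  out
}

# symmetric (half-sample) reflection of a 1-based index
reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# dense 2-D Gaussian convolution with reflected borders, kernel cut at 4 sigma
gauss_blur_oracle <- function(img, sigma) {
  rad <- max(1, ceiling(4 * sigma))
  k1 <- exp(-0.5 * ((-rad:rad) / sigma)^2)
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (t in -rad:rad) {
        for (u in -rad:rad) {
          acc <- acc + K[t + rad + 1, u + rad + 1] *
            img[reflect1(i + t, h), reflect1(j + u, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# windowed local mean with reflected borders, direct per-pixel summation
window_mean_oracle <- function(img, block) {
  r <- block %/% 2
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (t in -r:r) {
        for (u in -r:r) {
          acc <- acc + img[reflect1(i + t, h), reflect1(j + u, w)]
        }
      }
      out[i, j] <- acc / block^2
    }
  }
  out
}

pm10_mixture <- c(PM1 = 0, PM2_5 = 0, PM10 = 1)

# small clean scene helper used across detection tests
make_scene <- function(n, seed, side = 500, min_gap_px = 2,
                       mixture = pm10_mixture, background_sigma = 2) {
  spec <- sensor_image_spec(side, side, background_sigma = background_sigma)
  parts <- sample_particles(spec, n, mixture = mixture,
                            min_gap_px = min_gap_px, seed = seed)
  out <- render_sensor_image(spec, parts, seed = seed + 1L)
  list(spec = spec, parts = parts, image = out$image, truth = out$truth)
}
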