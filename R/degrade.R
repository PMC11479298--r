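#' Camera-degradation configuration
#'
#' Bundles the three degradation models — additive Gaussian sensor noise,
#' spatially varying focus blur, and a white-balance temperature shift — any
#' of which may be absent (absent components are the identity). When composed
#' with [compose_degradations()], the fixed order mimics the physical capture
#' chain: focus blur (optics), then white balance (in-camera processing),
#' then Gaussian noise (sensor electronics).
#'
#' @param gaussian NULL or a list/named vector with `mean` and `variance`
#'   (digital numbers on the 0-255 scale; DN and DN^2).
#' @param focus_blur NULL or a list/named vector with `focus_area` (percent
#'   of each image dimension kept sharp, in (0,100]) and `strength`
#'   (blur sigma in pixels, >= 0).
#' @param white_balance NULL or a list/named vector with `temperature`
#'   (signed; negative values cool the image).
#' @param seed Integer seed used for the Gaussian-noise stage.
#' @return An object of class `degradation_config`.
#' @examples
#' cfg <- degradation_config(gaussian = list(mean = 5, variance = 8),
#'                           white_balance = list(temperature = -20), seed = 3)
#' @export
degradation_config <- function(gaussian = NULL, focus_blur = NULL,
                               white_balance = NULL, seed = 1) {
  if (!is.null(gaussian)) {
    gaussian <- as.list(gaussian)
    stopifnot(all(c("mean", "variance") %in% names(gaussian)))
    if (gaussian$variance < 0) stop("variance must be >= 0", call. = FALSE)
  }
  if (!is.null(focus_blur)) {
    focus_blur <- as.list(focus_blur)
    stopifnot(all(c("focus_area", "strength") %in% names(focus_blur)))
    if (focus_blur$focus_area <= 0 || focus_blur$focus_area > 100) {
      stop("focus_area must be in (0, 100]", call. = FALSE)
    }
    if (focus_blur$strength < 0) stop("strength must be >= 0", call. = FALSE)
  }
  if (!is.null(white_balance)) {
    white_balance <- as.list(white_balance)
    stopifnot("temperature" %in% names(white_balance))
  }
  structure(list(gaussian = gaussian, focus_blur = focus_blur,
                 white_balance = white_balance, seed = as.integer(seed)),
            class = "degradation_config")
}

#' Additive Gaussian sensor noise
#'
#' Adds per-pixel independent N(mean, variance) noise in 0-255 digital-number
#' units to every channel, then clips to \[0, 255\] and re-quantizes to 8
#' bits. `mean = 0, variance = 0` is an exact identity.
#'
#' @param image Numeric matrix or h x w x 3 array, values 0-255.
#' @param mean,variance Noise mean (DN) and variance (DN^2, >= 0).
#' @param seed Integer seed; deterministic per seed.
#' @return Degraded image of the same dimensions.
#' @export
add_gaussian_noise <- function(image, mean, variance, seed = 1) {
  assert_image(image)
  if (variance < 0) stop("variance must be >= 0", call. = FALSE)
  if (mean == 0 && variance == 0) return(image)
  withr::with_seed(as.integer(seed), {
    add_noise_quantize_cpp(image, mean, sqrt(variance))
  })
}

#' Spatially varying focus blur
#'
#' Keeps a centred rectangle covering `focus_area` percent of each image
#' dimension sharp and applies a Gaussian blur of sigma `strength` pixels
#' (kernel truncated at 4 sigma, reflected borders) outside it, with a
#' raised-cosine transition band 3 sigma wide so no seam is visible.
#' `focus_area = 100` or `strength = 0` is an exact identity.
#'
#' @param image Numeric matrix or h x w x 3 array, values 0-255.
#' @param focus_area Percent of each dimension kept sharp, in (0, 100].
#' @param strength Blur sigma in pixels (>= 0).
#' @return Degraded image of the same dimensions.
#' @export
apply_focus_blur <- function(image, focus_area, strength) {
  assert_image(image)
  if (focus_area <= 0 || focus_area > 100) {
    stop("focus_area must be in (0, 100]", call. = FALSE)
  }
  if (strength < 0) stop("strength must be >= 0", call. = FALSE)
  if (focus_area == 100 || strength == 0) return(image)
  if (is.matrix(image)) {
    return(focus_blur_channel_cpp(image, focus_area, strength))
  }
  # synthetic sensor images enter the chain with three equal channels; blur
  # once and replicate in that case
  if (identical(image[, , 1], image[, , 2]) &&
      identical(image[, , 2], image[, , 3])) {
    ch <- focus_blur_channel_cpp(image[, , 1], focus_area, strength)
    return(grey_to_rgb8_cpp(ch))
  }
  out <- image
  for (c in 1:3) {
    out[, , c] <- focus_blur_channel_cpp(image[, , c], focus_area, strength)
  }
  out
}

#' White-balance temperature shift
#'
#' Linear per-channel gain model: red gain `1 + 0.01 * temperature`, blue
#' gain `1 - 0.01 * temperature`, green unchanged (bit-identical); gains are
#' clamped at 0 and results clipped to \[0, 255\]. Negative temperatures cool
#' the image (red down, blue up). `temperature = 0` is an exact identity.
#'
#' @param image h x w x 3 array, values 0-255.
#' @param temperature Signed temperature shift (the study range is -1 to -20).
#' @return Degraded image of the same dimensions.
#' @export
adjust_white_balance <- function(image, temperature) {
  assert_image(image)
  if (!is_rgb_image(image)) {
    stop("white balance requires a 3-channel image", call. = FALSE)
  }
  if (temperature == 0) return(image)
  red_gain <- max(0, 1 + 0.01 * temperature)
  blue_gain <- max(0, 1 - 0.01 * temperature)
  d <- dim(image)
  wb_gains_cpp(image, d[1], d[2], red_gain, blue_gain)
}

#' Compose camera degradations in capture-chain order
#'
#' Applies, in order, focus blur (optics), white balance (camera processing)
#' and Gaussian noise (sensor electronics), skipping absent components.
#' Deterministic for a fixed `config$seed`.
#'
#' @param image h x w x 3 array, values 0-255.
#' @param config A [degradation_config()].
#' @return Degraded image of the same dimensions.
#' @export
compose_degradations <- function(image, config) {
  stopifnot(inherits(config, "degradation_config"))
  if (!is.null(config$focus_blur)) {
    image <- apply_focus_blur(image, config$focus_blur$focus_area,
                              config$focus_blur$strength)
  }
  if (!is.null(config$white_balance)) {
    image <- adjust_white_balance(image, config$white_balance$temperature)
  }
  if (!is.null(config$gaussian)) {
    image <- add_gaussian_noise(image, config$gaussian$mean,
                                config$gaussian$variance, config$seed)
  }
  image
}
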