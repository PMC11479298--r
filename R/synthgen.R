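#' Specification of a synthetic paper-sensor image
#'
#' Describes the geometry, resolution and background of a synthetic sensor
#' photograph. The physical sensor is a square of paper (default 6 cm on a
#' side) coated with petroleum jelly; at the default working resolution of
#' 1 pixel per micrometre a full frame would be 60,000 px wide, so generated
#' images are sub-frame crops and their imaged area in cm^2 is tracked for
#' dot-density computations.
#'
#' @param width_px,height_px Image dimensions in pixels (each >= 16).
#' @param resolution_px_per_um Pixels per micrometre (default 1).
#' @param frame_size_cm Side of the square sensor frame in cm (default 6).
#' @param background_mean Mean background grey level, 200-255 (white paper).
#' @param background_sigma Standard deviation of the Gaussian paper-texture
#'   jitter in digital numbers (0 disables the texture).
#' @return An object of class `sensor_image_spec`.
#' @examples
#' spec <- sensor_image_spec(500, 500)
#' imaged_area_cm2(spec)
#' @export
sensor_image_spec <- function(width_px, height_px,
                              resolution_px_per_um = 1,
                              frame_size_cm = 6,
                              background_mean = 245,
                              background_sigma = 2) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (width_px < 16L || height_px < 16L) {
    stop("image dimensions must be at least 16 x 16 px", call. = FALSE)
  }
  if (resolution_px_per_um <= 0 || !is.finite(resolution_px_per_um)) {
    stop("resolution_px_per_um must be positive and finite", call. = FALSE)
  }
  if (frame_size_cm <= 0) stop("frame_size_cm must be positive", call. = FALSE)
  if (background_mean < 200 || background_mean > 255) {
    stop("background_mean must be in [200, 255] (white paper)", call. = FALSE)
  }
  if (background_sigma < 0) {
    stop("background_sigma must be non-negative", call. = FALSE)
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         resolution_px_per_um = resolution_px_per_um,
         frame_size_cm = frame_size_cm,
         background_mean = as.integer(round(background_mean)),
         background_sigma = background_sigma,
         bit_depth = 8L),
    class = "sensor_image_spec"
  )
}

#' @export
print.sensor_image_spec <- function(x, ...) {
  cat(sprintf(
    "<sensor_image_spec> %d x %d px at %g px/um (%.4g cm^2 of a %g cm frame)\n",
    x$width_px, x$height_px, x$resolution_px_per_um, imaged_area_cm2(x),
    x$frame_size_cm))
  cat(sprintf("  background: mean %d, sigma %g, %d-bit\n",
              x$background_mean, x$background_sigma, x$bit_depth))
  invisible(x)
}

#' Imaged area of a sensor crop in cm^2
#'
#' `area_cm2 = width_px * height_px / (resolution^2 * 1e8)`, where resolution
#' is in px/um and 1e8 converts um^2 to cm^2.
#'
#' @param spec A [sensor_image_spec()].
#' @return Area in cm^2.
#' @export
imaged_area_cm2 <- function(spec) {
  stopifnot(inherits(spec, "sensor_image_spec"))
  spec$width_px * spec$height_px / (spec$resolution_px_per_um^2 * 1e8)
}

# diameter strata (um) used for ground-truth sampling; classes are disjoint
# here even though reporting treats PM1/PM2.5 as nested inside PM10
pm_strata <- list(PM1 = c(0, 1), PM2_5 = c(1, 2.5), PM10 = c(2.5, 10))

pm_levels <- c("PM1", "PM2_5", "PM10", "OVERSIZE")

#' Sample ground-truth particles for a synthetic sensor image
#'
#' Draws `n` particles: a PM class per the mixture weights, a diameter uniform
#' within the class stratum (PM1 in (0,1], PM2.5 in (1,2.5], PM10 in
#' (2.5,10] um), a grey level uniform on 0-120 (black and grey dots), and a
#' centre uniform over the image interior subject to a minimum edge-to-edge
#' gap between disks. Placement uses bounded rejection sampling and fails
#' with a placement-infeasible error when the requested density cannot be
#' achieved.
#'
#' @param spec A [sensor_image_spec()].
#' @param n Number of particles (>= 0).
#' @param mixture Named non-negative weights for `PM1`, `PM2_5`, `PM10`
#'   (need not sum to 1; default uniform).
#' @param min_gap_px Minimum edge-to-edge separation between disks in pixels;
#'   0 permits overlaps.
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @param max_attempts Total rejection-sampling attempt budget.
#' @return A data frame with columns `id`, `center_x_px`, `center_y_px`,
#'   `diameter_um`, `grey_level`, `pm_class`.
#' @examples
#' spec <- sensor_image_spec(500, 500)
#' gt <- sample_particles(spec, 20, seed = 1)
#' table(gt$pm_class)
#' @export
sample_particles <- function(spec, n, mixture = c(PM1 = 1, PM2_5 = 1, PM10 = 1),
                             min_gap_px = 1, seed = 1,
                             max_attempts = max(1e4, 200 * n)) {
  stopifnot(inherits(spec, "sensor_image_spec"))
  n <- as.integer(n)
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (min_gap_px < 0) stop("min_gap_px must be non-negative", call. = FALSE)
  mixture <- mixture[c("PM1", "PM2_5", "PM10")]
  if (anyNA(mixture)) {
    stop("mixture must name weights for PM1, PM2_5 and PM10", call. = FALSE)
  }
  if (any(mixture < 0) || sum(mixture) <= 0) {
    stop("invalid mixture: weights must be non-negative, not all zero",
         call. = FALSE)
  }
  empty <- data.frame(id = integer(), center_x_px = numeric(),
                      center_y_px = numeric(), diameter_um = numeric(),
                      grey_level = integer(),
                      pm_class = factor(character(), levels = pm_levels))
  if (n == 0L) return(empty)
  withr::with_seed(as.integer(seed), {
    cls <- sample(names(pm_strata), n, replace = TRUE,
                  prob = mixture / sum(mixture))
    lo <- vapply(pm_strata[cls], `[`, numeric(1), 1L)
    hi <- vapply(pm_strata[cls], `[`, numeric(1), 2L)
    diameter_um <- runif(n, lo, hi)
    grey_level <- sample.int(121L, n, replace = TRUE) - 1L
    r_px <- diameter_um * spec$resolution_px_per_um / 2
    centers <- place_centers_cpp(spec$height_px, spec$width_px, r_px,
                                 min_gap_px, max_attempts)
    data.frame(id = seq_len(n),
               center_x_px = centers[, 2],
               center_y_px = centers[, 1],
               diameter_um = diameter_um,
               grey_level = grey_level,
               pm_class = factor(cls, levels = pm_levels))
  })
}

count_by_class <- function(pm_class) {
  tab <- table(factor(pm_class, levels = c("PM1", "PM2_5", "PM10")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Render a synthetic sensor image from ground-truth particles
#'
#' Paints each particle as an anti-aliased filled disk of pixel diameter
#' `diameter_um * resolution_px_per_um` at its grey level over a near-white
#' background (`background_mean` plus optional Gaussian texture of sd
#' `background_sigma`, clipped to 0-255). The result is an 8-bit RGB array
#' with three identical channels, plus a ground-truth record.
#'
#' @param spec A [sensor_image_spec()].
#' @param particles Data frame as returned by [sample_particles()].
#' @param seed Integer seed for the background texture.
#' @return A list with elements `image` (h x w x 3 array, values 0-255) and
#'   `truth` (class `ground_truth`: `particles`, `n_total`, `n_by_class`,
#'   `spec`, `seed`).
#' @examples
#' spec <- sensor_image_spec(64, 64, background_sigma = 0)
#' out <- render_sensor_image(spec, sample_particles(spec, 3, seed = 2), seed = 2)
#' dim(out$image)
#' @export
render_sensor_image <- function(spec, particles, seed = 1) {
  stopifnot(inherits(spec, "sensor_image_spec"))
  h <- spec$height_px
  w <- spec$width_px
  if (nrow(particles) > 0) {
    oob <- particles$center_x_px < 0 | particles$center_x_px > w |
      particles$center_y_px < 0 | particles$center_y_px > h
    if (any(oob)) {
      stop(sprintf("particle(s) out of image bounds: %s",
                   paste(particles$id[oob], collapse = ", ")), call. = FALSE)
    }
  }
  grey <- withr::with_seed(as.integer(seed), {
    bg <- matrix(as.numeric(spec$background_mean), h, w)
    if (spec$background_sigma > 0) {
      bg <- bg + rnorm(h * w, 0, spec$background_sigma)
    }
    bg
  })
  if (nrow(particles) > 0) {
    r_px <- particles$diameter_um * spec$resolution_px_per_um / 2
    grey <- render_disks_cpp(grey, particles$center_y_px,
                             particles$center_x_px, r_px,
                             as.numeric(particles$grey_level))
  }
  img <- grey_to_rgb8_cpp(grey)
  truth <- structure(
    list(particles = particles,
         n_total = nrow(particles),
         n_by_class = count_by_class(particles$pm_class),
         spec = spec,
         seed = as.integer(seed)),
    class = "ground_truth"
  )
  list(image = img, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d particles (PM1 %d, PM2.5 %d, PM10 %d), seed %d\n",
              x$n_total, x$n_by_class[["PM1"]], x$n_by_class[["PM2_5"]],
              x$n_by_class[["PM10"]], x$seed))
  invisible(x)
}

#' Generate a batch of synthetic sensor images with ground truth
#'
#' Runs the generator (and optionally the degradation chain) over a list of
#' grid cells and writes one PNG image, one ground-truth JSON file and one
#' flat CSV mirror per cell, plus a manifest CSV linking them. Output is
#' deterministic: re-running with the same grid and seeds reproduces every
#' file byte for byte.
#'
#' @param grid A list of cells; each cell is a list with elements `spec`
#'   (a [sensor_image_spec()]), `n` (particle count), and optionally
#'   `mixture`, `min_gap_px`, `degradation` (a [degradation_config()] or
#'   NULL) and `seed`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame, invisibly. Columns: `cell`, `image_path`,
#'   `truth_path`, `n_particles`, `gaussian_mean`, `gaussian_variance`,
#'   `blur_focus_area`, `blur_strength`, `wb_temperature`, `seed`.
#' @export
generate_dataset <- function(grid, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  rows <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    cell <- grid[[k]]
    res <- tryCatch({
      seed <- if (is.null(cell$seed)) k else cell$seed
      mixture <- if (is.null(cell$mixture)) {
        c(PM1 = 1, PM2_5 = 1, PM10 = 1)
      } else cell$mixture
      min_gap <- if (is.null(cell$min_gap_px)) 1 else cell$min_gap_px
      parts <- sample_particles(cell$spec, cell$n, mixture, min_gap, seed)
      out <- render_sensor_image(cell$spec, parts, seed)
      img <- out$image
      dg <- cell$degradation
      if (!is.null(dg)) img <- compose_degradations(img, dg)
      image_path <- file.path(out_dir, sprintf("cell_%04d.png", k))
      truth_path <- file.path(out_dir, sprintf("cell_%04d.json", k))
      csv_path <- file.path(out_dir, sprintf("cell_%04d.csv", k))
      write_sensor_image(img, image_path)
      write_ground_truth(out$truth, truth_path, csv_path)
      data.frame(
        cell = k, image_path = image_path, truth_path = truth_path,
        n_particles = cell$n,
        gaussian_mean = if (!is.null(dg$gaussian)) dg$gaussian$mean else NA_real_,
        gaussian_variance = if (!is.null(dg$gaussian)) dg$gaussian$variance else NA_real_,
        blur_focus_area = if (!is.null(dg$focus_blur)) dg$focus_blur$focus_area else NA_real_,
        blur_strength = if (!is.null(dg$focus_blur)) dg$focus_blur$strength else NA_real_,
        wb_temperature = if (!is.null(dg$white_balance)) dg$white_balance$temperature else NA_real_,
        seed = seed)
    }, error = function(e) {
      stop(sprintf("grid cell %d failed: %s", k, conditionMessage(e)),
           call. = FALSE)
    })
    rows[[k]] <- res
  }
  manifest <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cell = integer(), image_path = character(),
               truth_path = character(), n_particles = integer(),
               gaussian_mean = numeric(), gaussian_variance = numeric(),
               blur_focus_area = numeric(), blur_strength = numeric(),
               wb_temperature = numeric(), seed = integer())
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
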