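#' Read an 8-bit sensor photograph
#'
#' Supports lossless PNG and TIFF. Pixel values are returned on the 0-255
#' integer scale; 16-bit TIFF input is rescaled to 8 bits by
#' `round(value / 65535 * 255)`. JPEG and other lossy formats are rejected:
#' the pipeline's quality contracts are stated on lossless images.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return h x w x 3 array (or h x w matrix for single-channel files),
#'   values 0-255.
#' @export
read_sensor_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = stop("unsupported format: JPEG is lossy; supply PNG or TIFF",
                call. = FALSE),
    stop(sprintf("unsupported format '.%s'; supply PNG or TIFF", ext),
         call. = FALSE)
  )
  img <- round(raw * 255)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha if present
  }
  img
}

#' Write an 8-bit sensor image losslessly
#'
#' PNG or TIFF by file extension; write-then-read round-trips bit-identically.
#'
#' @param image Numeric matrix or h x w x 3 array, integer values 0-255.
#' @param path Destination path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_sensor_image <- function(image, path) {
  assert_image(image)
  if (any(image < 0 | image > 255) || any(image != round(image))) {
    stop("image values must be integers in [0, 255]", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  scaled <- image / 255
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    stop(sprintf("unsupported format '.%s'; use PNG or TIFF", ext),
         call. = FALSE)
  )
  invisible(path)
}

#' Write ground truth as JSON (with optional flat CSV mirror)
#'
#' The JSON object carries the particle records (fields `id`, `center_x_px`,
#' `center_y_px`, `diameter_um`, `grey_level`, `pm_class`; 0-based
#' row/column pixel coordinates, origin top-left), the counts, the image
#' specification and the seed.
#'
#' @param truth A `ground_truth` object from [render_sensor_image()].
#' @param json_path Destination JSON path.
#' @param csv_path Optional destination for a flat CSV of the particle table.
#' @return `json_path`, invisibly.
#' @export
write_ground_truth <- function(truth, json_path, csv_path = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  particles <- truth$particles
  particles$pm_class <- as.character(particles$pm_class)
  payload <- list(
    coordinate_convention = "0-based (row, column), origin top-left",
    n_total = truth$n_total,
    n_by_class = as.list(truth$n_by_class),
    seed = truth$seed,
    spec = unclass(truth$spec),
    particles = particles
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(csv_path)) write.csv(particles, csv_path, row.names = FALSE)
  invisible(json_path)
}

#' Read ground truth back from JSON
#'
#' @param json_path Path written by [write_ground_truth()].
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  particles <- as.data.frame(payload$particles)
  if (nrow(particles) == 0) {
    particles <- data.frame(id = integer(), center_x_px = numeric(),
                            center_y_px = numeric(), diameter_um = numeric(),
                            grey_level = integer(), pm_class = character())
  }
  particles$pm_class <- factor(particles$pm_class, levels = pm_levels)
  s <- payload$spec
  spec <- sensor_image_spec(s$width_px, s$height_px, s$resolution_px_per_um,
                            s$frame_size_cm, s$background_mean,
                            s$background_sigma)
  structure(list(particles = particles,
                 n_total = as.integer(payload$n_total),
                 n_by_class = unlist(payload$n_by_class),
                 spec = spec,
                 seed = as.integer(payload$seed)),
            class = "ground_truth")
}

run_config_schema <- list(
  common = c("subcommand", "seed", "log_level", "out"),
  generate = c("width", "height", "resolution", "n_particles", "mixture",
               "min_gap_px", "background_mean", "background_sigma",
               "gaussian", "focus_blur", "white_balance"),
  degrade = c("in", "gaussian", "focus_blur", "white_balance"),
  detect = c("in", "px_per_cm", "frame_cm", "frame_px", "preblur_sigma_px",
             "adaptive_block_px", "adaptive_offset", "min_area_px",
             "target_resolution", "bicubic_a"),
  classify = c("density"),
  sweep = c("particle_counts", "n_seeds", "width", "height", "families")
)

run_config_defaults <- list(seed = 1L, log_level = "info", out = ".")

#' Load and validate a run configuration file
#'
#' YAML key-value file with a mandatory `subcommand` key (one of `generate`,
#' `degrade`, `detect`, `classify`, `sweep`); keys not documented for that
#' subcommand are rejected by name, and missing optional keys are filled with
#' defaults (`seed` 1, `log_level` "info", `out` ".").
#'
#' @param path Path to a YAML configuration file.
#' @return A validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(cfg$subcommand)) {
    stop("config must define a 'subcommand' key", call. = FALSE)
  }
  sub <- cfg$subcommand
  if (!sub %in% names(run_config_schema)[-1]) {
    stop(sprintf("unknown subcommand '%s' (expected one of %s)", sub,
                 paste(names(run_config_schema)[-1], collapse = ", ")),
         call. = FALSE)
  }
  allowed <- c(run_config_schema$common, run_config_schema[[sub]])
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s) for subcommand '%s': %s", sub,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  required <- switch(sub, degrade = "in", detect = "in", classify = "density",
                     character())
  missing_req <- setdiff(required, names(cfg))
  if (length(missing_req) > 0) {
    stop(sprintf("missing required config key(s) for subcommand '%s': %s",
                 sub, paste(missing_req, collapse = ", ")), call. = FALSE)
  }
  for (key in names(run_config_defaults)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- run_config_defaults[[key]]
  }
  structure(cfg, class = "run_config")
}

#' Run manifest: config hash, seed and library versions
#'
#' Two runs with equal manifests are guaranteed to produce equal outputs,
#' since every source of randomness is derived from the recorded seed.
#'
#' @param config Any configuration object (hashed via its JSON serialization).
#' @param seed The master seed of the run.
#' @return A one-row data frame with `config_hash`, `seed`, `package_version`
#'   and `r_version`.
#' @export
run_manifest <- function(config, seed) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  hash <- unname(tools::md5sum(tmp))
  data.frame(config_hash = hash, seed = as.integer(seed),
             package_version = as.character(utils::packageVersion("dustscan")),
             r_version = paste(R.version$major, R.version$minor, sep = "."))
}
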