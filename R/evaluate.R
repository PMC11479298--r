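#' Count-based detection accuracy
#'
#' `100 * detected / actual`, the percentage of the true particle count that
#' the pipeline detected. Values above 100 (over-detection, i.e. false
#' positives outnumbering misses) are returned as-is; callers can flag them
#' with `detected > actual`.
#'
#' @param detected Detected particle count(s), >= 0.
#' @param actual True particle count(s), > 0.
#' @return Accuracy in percent.
#' @examples
#' accuracy(926, 1000)
#' @export
accuracy <- function(detected, actual) {
  if (any(actual <= 0)) stop("actual must be positive", call. = FALSE)
  if (any(detected < 0)) stop("detected must be non-negative", call. = FALSE)
  100 * detected / actual
}

#' Noise-family grid at the study's parameter endpoints
#'
#' The five experiment families — Gaussian noise alone, focus blur alone,
#' white balance alone, Gaussian + white balance, and all three — each at the
#' mild and harsh endpoints of the studied parameter ranges (Gaussian mean
#' 1-5 with variance 4-8; focus area 100-70 with blur strength 1-4;
#' white-balance temperature -1 to -20).
#'
#' @return A named list of conditions; each condition is a list with `family`,
#'   `label` and the degradation component settings.
#' @export
noise_endpoint_grid <- function() {
  list(
    gaussian_mild = list(
      family = "gaussian", label = "mean 1, var 4",
      gaussian = list(mean = 1, variance = 4)),
    gaussian_harsh = list(
      family = "gaussian", label = "mean 5, var 8",
      gaussian = list(mean = 5, variance = 8)),
    blur_mild = list(
      family = "focus_blur", label = "area 100, strength 1",
      focus_blur = list(focus_area = 100, strength = 1)),
    blur_harsh = list(
      family = "focus_blur", label = "area 70, strength 4",
      focus_blur = list(focus_area = 70, strength = 4)),
    wb_mild = list(
      family = "white_balance", label = "temp -1",
      white_balance = list(temperature = -1)),
    wb_harsh = list(
      family = "white_balance", label = "temp -20",
      white_balance = list(temperature = -20)),
    gaussian_wb_mild = list(
      family = "gaussian_wb", label = "mean 1, var 4, temp -1",
      gaussian = list(mean = 1, variance = 4),
      white_balance = list(temperature = -1)),
    gaussian_wb_harsh = list(
      family = "gaussian_wb", label = "mean 5, var 8, temp -20",
      gaussian = list(mean = 5, variance = 8),
      white_balance = list(temperature = -20)),
    all_mild = list(
      family = "gaussian_blur_wb",
      label = "mean 1, var 4, area 100, strength 1, temp -1",
      gaussian = list(mean = 1, variance = 4),
      focus_blur = list(focus_area = 100, strength = 1),
      white_balance = list(temperature = -1)),
    all_harsh = list(
      family = "gaussian_blur_wb",
      label = "mean 5, var 8, area 70, strength 4, temp -20",
      gaussian = list(mean = 5, variance = 8),
      focus_blur = list(focus_area = 70, strength = 4),
      white_balance = list(temperature = -20))
  )
}

#' Configuration of an accuracy sweep
#'
#' @param particle_counts Particle counts per image (default 100 to 800 in
#'   steps of 100).
#' @param noise_grid Named list of noise conditions as produced by
#'   [noise_endpoint_grid()]; an empty list sweeps clean images under a single
#'   "clean" condition.
#' @param n_seeds Replicates per condition (>= 1).
#' @param spec Image specification for ordinary counts (default 2000 x 2000 px
#'   at 1 px/um).
#' @param large_spec Specification used for counts of
#'   `large_count_threshold` or more (default 4000 x 4000 px, keeping density
#'   comparable for the 10,000-particle condition).
#' @param large_count_threshold Count at which `large_spec` takes over.
#' @param extra_counts Named list mapping a family name to extra particle
#'   counts run only for that family (default: 10,000 for `white_balance`).
#' @param detection [detection_params()] used throughout.
#' @param mixture,min_gap_px Ground-truth sampling settings
#'   (see [sample_particles()]).
#' @param seed Master seed from which all per-run seeds are derived.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(particle_counts = seq(100, 800, by = 100),
                         noise_grid = noise_endpoint_grid(),
                         n_seeds = 10,
                         spec = sensor_image_spec(2000, 2000),
                         large_spec = sensor_image_spec(4000, 4000),
                         large_count_threshold = 1000,
                         extra_counts = list(white_balance = 10000),
                         detection = detection_params(),
                         mixture = c(PM1 = 1, PM2_5 = 1, PM10 = 1),
                         min_gap_px = 1,
                         seed = 1) {
  if (any(particle_counts <= 0)) {
    stop("particle_counts must be positive", call. = FALSE)
  }
  if (n_seeds < 1) stop("n_seeds must be >= 1", call. = FALSE)
  if (length(noise_grid) == 0) {
    noise_grid <- list(clean = list(family = "clean", label = "no noise"))
  }
  structure(list(particle_counts = as.integer(particle_counts),
                 noise_grid = noise_grid, n_seeds = as.integer(n_seeds),
                 spec = spec, large_spec = large_spec,
                 large_count_threshold = large_count_threshold,
                 extra_counts = extra_counts, detection = detection,
                 mixture = mixture, min_gap_px = min_gap_px,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

sweep_cells <- function(config) {
  cells <- list()
  for (cond_name in names(config$noise_grid)) {
    cond <- config$noise_grid[[cond_name]]
    counts <- config$particle_counts
    extra <- config$extra_counts[[cond$family]]
    if (!is.null(extra)) counts <- c(counts, as.integer(extra))
    for (n in counts) {
      for (rep in seq_len(config$n_seeds)) {
        cells[[length(cells) + 1L]] <-
          list(condition = cond_name, cond = cond, n = n, rep = rep)
      }
    }
  }
  cells
}

#' Run an accuracy sweep over noise conditions
#'
#' For every (condition x particle count x replicate): generate a clean
#' synthetic image, apply the condition's degradations, run the detection
#' pipeline and record the count accuracy. All randomness derives from
#' `config$seed`, so reruns reproduce the report exactly. A failing cell is
#' recorded with status `"error"` rather than dropped.
#'
#' @param config A [sweep_config()].
#' @param progress Print one line per condition as it completes.
#' @return An object of class `accuracy_report`: `rows` (one row per run:
#'   condition, family, label, n_particles, seed_index, detected, actual,
#'   accuracy_pct, over_detection, status) and `aggregates` (mean and sd of
#'   accuracy per condition x count).
#' @export
run_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  cells <- sweep_cells(config)
  seeds <- matrix(derive_seeds(config$seed, 3L * length(cells)), ncol = 3)
  rows <- vector("list", length(cells))
  last_cond <- ""
  for (k in seq_along(cells)) {
    cell <- cells[[k]]
    if (progress && cell$condition != last_cond) {
      message("condition: ", cell$condition)
      last_cond <- cell$condition
    }
    spec <- if (cell$n >= config$large_count_threshold) config$large_spec
            else config$spec
    row <- tryCatch({
      parts <- sample_particles(spec, cell$n, config$mixture,
                                config$min_gap_px, seeds[k, 1])
      out <- render_sensor_image(spec, parts, seeds[k, 2])
      img <- out$image
      cond <- cell$cond
      if (cond$family != "clean") {
        dg <- degradation_config(gaussian = cond$gaussian,
                                 focus_blur = cond$focus_blur,
                                 white_balance = cond$white_balance,
                                 seed = seeds[k, 3])
        img <- compose_degradations(img, dg)
      }
      res <- detect_particles(img, config$detection,
                              calibration_from_spec(spec))
      data.frame(condition = cell$condition, family = cell$cond$family,
                 label = cell$cond$label, n_particles = cell$n,
                 seed_index = cell$rep, detected = res$n_total,
                 actual = cell$n,
                 accuracy_pct = accuracy(res$n_total, cell$n),
                 over_detection = res$n_total > cell$n,
                 status = "ok")
    }, error = function(e) {
      data.frame(condition = cell$condition, family = cell$cond$family,
                 label = cell$cond$label, n_particles = cell$n,
                 seed_index = cell$rep, detected = NA_integer_,
                 actual = cell$n, accuracy_pct = NA_real_,
                 over_detection = NA, status = paste0("error: ",
                                                      conditionMessage(e)))
    })
    rows[[k]] <- row
  }
  rows <- do.call(rbind, rows)
  ok <- rows[rows$status == "ok", ]
  aggregates <- if (nrow(ok) > 0) {
    agg <- aggregate(accuracy_pct ~ condition + family + label + n_particles,
                     data = ok,
                     FUN = function(x) c(mean = mean(x), sd = sd(x)))
    data.frame(agg[, c("condition", "family", "label", "n_particles")],
               mean_accuracy_pct = agg$accuracy_pct[, "mean"],
               sd_accuracy_pct = agg$accuracy_pct[, "sd"])
  } else {
    data.frame(condition = character(), family = character(),
               label = character(), n_particles = integer(),
               mean_accuracy_pct = numeric(), sd_accuracy_pct = numeric())
  }
  structure(list(rows = rows, aggregates = aggregates, config = config),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %d runs over %d conditions\n",
              nrow(x$rows), length(unique(x$rows$condition))))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

#' Write a sweep report to disk
#'
#' Writes the per-run rows and the per-condition aggregates as CSV, plus one
#' accuracy-versus-particle-count figure (PNG) per experiment family. CSV
#' output is byte-identical across reruns of the same report.
#'
#' @param report An [run_sweep()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_sweep_report <- function(report, out_dir) {
  stopifnot(inherits(report, "accuracy_report"))
  if (nrow(report$rows) == 0) {
    stop("empty report: nothing to write", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  rows_path <- file.path(out_dir, "sweep_rows.csv")
  agg_path <- file.path(out_dir, "sweep_aggregates.csv")
  write.csv(report$rows, rows_path, row.names = FALSE)
  write.csv(report$aggregates, agg_path, row.names = FALSE)
  paths <- c(rows_path, agg_path)
  agg <- report$aggregates
  for (fam in unique(agg$family)) {
    sub <- agg[agg$family == fam, ]
    fig_path <- file.path(out_dir, sprintf("accuracy_%s.png", fam))
    grDevices::png(fig_path, width = 800, height = 600)
    tryCatch({
      conds <- unique(sub$condition)
      cols <- seq_along(conds)
      graphics::plot(NA, xlim = range(sub$n_particles),
                     ylim = c(0, max(100, sub$mean_accuracy_pct)),
                     xlab = "particles per image", ylab = "accuracy (%)",
                     main = sprintf("Detection accuracy: %s", fam), log = "x")
      for (i in seq_along(conds)) {
        s <- sub[sub$condition == conds[i], ]
        s <- s[order(s$n_particles), ]
        graphics::lines(s$n_particles, s$mean_accuracy_pct, col = cols[i],
                        type = "b", pch = 19)
      }
      graphics::legend("bottomleft", legend = conds, col = cols, lty = 1,
                       pch = 19, bty = "n")
    }, finally = grDevices::dev.off())
    paths <- c(paths, fig_path)
  }
  invisible(paths)
}
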