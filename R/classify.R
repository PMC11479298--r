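#' PM class from particle diameter
#'
#' Assigns the particulate-matter class from the (equivalent) diameter in
#' micrometres, with inclusive upper bounds: PM1 for d <= 1, PM2.5 for
#' 1 < d <= 2.5, PM10 for 2.5 < d <= 10, and OVERSIZE above 10 um. The
#' labels are disjoint strata; in reporting the classes nest, i.e. every PM1
#' or PM2.5 particle also counts towards PM10 totals (see
#' [detect_particles()]'s `n_pm10`).
#'
#' @param diameter_um Positive diameter(s) in micrometres.
#' @return Factor with levels `PM1`, `PM2_5`, `PM10`, `OVERSIZE`.
#' @examples
#' pm_class(c(0.5, 2.5, 10, 10.01))
#' @export
pm_class <- function(diameter_um) {
  if (length(diameter_um) == 0) {
    return(factor(character(), levels = pm_levels))
  }
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0)) {
    stop("diameter_um must be positive and finite", call. = FALSE)
  }
  cls <- ifelse(diameter_um <= 1, "PM1",
         ifelse(diameter_um <= 2.5, "PM2_5",
         ifelse(diameter_um <= 10, "PM10", "OVERSIZE")))
  factor(cls, levels = pm_levels)
}

dust_levels <- c("Low", "Medium", "High", "Very high")

#' Dust-scale pollution level from dot density
#'
#' Maps a dot density (particles per cm^2 of sensor area) to the four-level
#' dust scale: fewer than 11 dots per cm^2 is Low, 11-25 Medium, 26-50 High
#' and more than 50 Very high. The published bands are stated on integers;
#' real-valued densities use the half-open convention \[0,11), \[11,26),
#' \[26,51), \[51,Inf) so that integer densities match the table exactly.
#'
#' @param dots_per_cm2 Non-negative density (or vector of densities).
#' @return Ordered factor with levels `Low < Medium < High < Very high`.
#' @examples
#' dust_scale_level(c(10, 11, 26, 55))
#' @export
dust_scale_level <- function(dots_per_cm2) {
  if (any(!is.finite(dots_per_cm2)) || any(dots_per_cm2 < 0)) {
    stop("dots_per_cm2 must be non-negative and finite", call. = FALSE)
  }
  cut(dots_per_cm2, breaks = c(0, 11, 26, 51, Inf), labels = dust_levels,
      right = FALSE, ordered_result = TRUE)
}

#' Dot density in dots per cm^2
#'
#' @param n_total Number of detected dots (>= 0).
#' @param area_cm2 Imaged sensor area in cm^2 (> 0).
#' @return `n_total / area_cm2`.
#' @examples
#' dot_density(36, 36)   # unit density over a full 6 x 6 cm sensor
#' @export
dot_density <- function(n_total, area_cm2) {
  if (any(area_cm2 <= 0)) stop("area_cm2 must be positive", call. = FALSE)
  if (any(n_total < 0)) stop("n_total must be non-negative", call. = FALSE)
  n_total / area_cm2
}
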