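# Small shared helpers.

#' Round half away from zero at .5
#'
#' Counts produced by multi-year averaging and by transect downscaling are
#' integerized with a half-up rule (2.5 -> 3), unlike base `round()` which
#' rounds half to even. Applied once, at the final integerization step.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4))
round_half_up <- function(x) floor(x + 0.5)

# Equidistant cylindrical (plate carree) projection to kilometres, anchored
# at a reference latitude. Adequate at the sub-degree extents of a reef
# system; only relative distances are ever used.
KM_PER_DEGREE <- 111.32

project_planar_km <- function(longitude, latitude, lat0) {
  list(
    x = longitude * KM_PER_DEGREE * cos(lat0 * pi / 180),
    y = latitude * KM_PER_DEGREE
  )
}

# Pairwise planar distance matrix (km) between rows of (lon, lat).
pairwise_dist_km <- function(longitude, latitude, lat0 = mean(latitude)) {
  p <- project_planar_km(longitude, latitude, lat0)
  as.matrix(stats::dist(cbind(p$x, p$y)))
}

# Quadratic-term naming convention: `<predictor>_sq`.
sq_name <- function(x) paste0(x, "_sq")

is_sq_name <- function(x) grepl("_sq$", x)

base_name <- function(x) sub("_sq$", "", x)
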