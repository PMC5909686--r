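# Per-site predictor construction: nearest-grid-node assignment, distances to
# boundary polylines, mean-centering and quadratic expansion.

#' Assign sites to their nearest predictor-grid node
#'
#' Each site is mapped to the grid node minimizing planar distance under an
#' equidistant cylindrical projection anchored at the mean latitude of sites
#' and nodes. Ties are broken by the lowest `node_id`.
#'
#' @param sites Tibble with `longitude`, `latitude` (decimal degrees).
#' @param grid Predictor grid tibble with `node_id`, `longitude`, `latitude`.
#' @return Tibble with one row per site: any site identifier columns present,
#'   plus `node_id` and `node_distance_km`.
#' @export
nearest_node_assign <- function(sites, grid) {
  if (nrow(grid) == 0) abort("empty predictor grid")
  lat0 <- mean(c(sites$latitude, grid$latitude))
  ps <- project_planar_km(sites$longitude, sites$latitude, lat0)
  pg <- project_planar_km(grid$longitude, grid$latitude, lat0)
  ord <- order(grid$node_id)  # tie-break independent of row order
  gx <- pg$x[ord]; gy <- pg$y[ord]; gid <- grid$node_id[ord]
  idx <- vapply(seq_along(ps$x), function(i) {
    d2 <- (gx - ps$x[i])^2 + (gy - ps$y[i])^2
    m <- min(d2)
    # ties (to floating-point slack) break to the lowest node_id
    which(d2 <= m + 1e-9 * (m + 1e-12))[1]
  }, integer(1))
  keep <- intersect(c("system_id", "reef_id", "site_id"), names(sites))
  out <- sites[, keep, drop = FALSE]
  out$node_id <- gid[idx]
  out$node_distance_km <-
    sqrt((gx[idx] - ps$x)^2 + (gy[idx] - ps$y)^2)
  tibble::as_tibble(out)
}

#' Shortest planar distance from sites to a boundary polyline
#'
#' Minimum point-to-segment distance in kilometres under an equidistant
#' cylindrical projection anchored at the mean latitude of the domain. Used
#' for the `coast` and `barrier` spatial predictors.
#'
#' @param sites Tibble with `longitude`, `latitude`.
#' @param boundary Polyline: a two-column matrix or data frame of vertex
#'   `longitude`, `latitude` (in order, `>= 2` vertices).
#' @param lat0 Projection anchor latitude; defaults to the mean latitude of
#'   sites and vertices.
#' @return Numeric vector of distances (km), one per site.
#' @export
distance_to_boundary <- function(sites, boundary, lat0 = NULL) {
  b <- as.matrix(as.data.frame(boundary)[, 1:2])
  if (nrow(b) < 2) abort("boundary polyline needs at least 2 vertices")
  if (any(!is.finite(b))) abort("boundary polyline has non-finite vertices")
  lat0 <- lat0 %||% mean(c(sites$latitude, b[, 2]))
  p <- project_planar_km(sites$longitude, sites$latitude, lat0)
  v <- project_planar_km(b[, 1], b[, 2], lat0)
  n_seg <- nrow(b) - 1
  d2 <- matrix(Inf, length(p$x), n_seg)
  for (s in seq_len(n_seg)) {
    ax <- v$x[s]; ay <- v$y[s]
    bx <- v$x[s + 1]; by <- v$y[s + 1]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx^2 + dy^2
    t <- if (len2 == 0) rep(0, length(p$x)) else
      pmin(1, pmax(0, ((p$x - ax) * dx + (p$y - ay) * dy) / len2))
    d2[, s] <- (p$x - (ax + t * dx))^2 + (p$y - (ay + t * dy))^2
  }
  sqrt(apply(d2, 1, min))
}

#' Build a design-ready predictor set
#'
#' Mean-centres each predictor and adds raw (non-orthogonal) quadratic columns
#' (`<name>_sq`, squares of the centred values) for the predictors modelled
#' with second-order polynomials. Centering constants and per-predictor
#' calibration ranges (min/max of the centred values over these rows) are
#' stored so that a target system can later be expressed in the reference
#' system's centred coordinates and extrapolation can be clipped.
#'
#' @param data Tibble of per-site (or per-node) rows carrying the predictor
#'   columns; non-predictor columns are passed through unchanged.
#' @param predictors Character vector of predictor column names to centre.
#' @param quadratic Predictors that get a quadratic column (intersected with
#'   `predictors`); default: the boundary distances, depth and temperature.
#' @param centers Optional named vector of centering constants from a
#'   reference predictor set ([predictor_centers()]); when supplied, these are
#'   used instead of the column means — the transfer contract: target data are
#'   centred with the reference system's constants.
#' @return A `predictor_set`: list with `data` (input plus centred columns and
#'   quadratics), `centers`, `ranges` (tibble of calibration min/max per
#'   centred predictor), `predictors`, `quadratic`.
#' @export
build_predictor_set <- function(data, predictors,
                                quadratic = c("coast", "barrier", "depth",
                                              "sst_av"),
                                centers = NULL) {
  missing_cols <- setdiff(predictors, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing predictor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  quadratic <- intersect(quadratic, predictors)
  if (is.null(centers)) {
    constant <- predictors[vapply(predictors, function(p) {
      sd(data[[p]]) == 0
    }, logical(1))]
    if (length(constant) > 0) {
      abort(paste0("constant predictor column(s): ",
                   paste(constant, collapse = ", ")))
    }
    centers <- vapply(predictors, function(p) mean(data[[p]]), numeric(1))
  } else {
    missing_c <- setdiff(predictors, names(centers))
    if (length(missing_c) > 0) {
      abort(paste0("no centering constant for: ",
                   paste(missing_c, collapse = ", ")))
    }
    centers <- centers[predictors]
  }
  out <- data
  for (p in predictors) {
    out[[p]] <- data[[p]] - centers[[p]]
    if (p %in% quadratic) out[[sq_name(p)]] <- out[[p]]^2
  }
  ranges <- tibble::tibble(
    predictor = predictors,
    min = unname(vapply(predictors, function(p) min(out[[p]]), numeric(1))),
    max = unname(vapply(predictors, function(p) max(out[[p]]), numeric(1)))
  )
  structure(
    list(data = out, centers = centers, ranges = ranges,
         predictors = predictors, quadratic = quadratic),
    class = "predictor_set"
  )
}

#' @export
print.predictor_set <- function(x, ...) {
  cat("<predictor_set> ", nrow(x$data), " rows, ", length(x$predictors),
      " centred predictors (quadratic: ",
      paste(x$quadratic, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Centering constants of a predictor set
#'
#' @param pset A `predictor_set`.
#' @return Named numeric vector of centering constants.
#' @export
predictor_centers <- function(pset) {
  stopifnot(inherits(pset, "predictor_set"))
  pset$centers
}

#' Serialize a predictor set's centering constants and calibration ranges
#'
#' JSON sidecar making transfer runs reproducible without the fitting data.
#'
#' @param pset A `predictor_set`.
#' @param path Output path (.json).
#' @return Invisibly, `path`.
#' @export
write_predictor_meta <- function(pset, path) {
  stopifnot(inherits(pset, "predictor_set"))
  jsonlite::write_json(
    list(centers = as.list(pset$centers), ranges = pset$ranges,
         quadratic = pset$quadratic),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
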