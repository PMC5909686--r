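# Synthetic twin-system generator.
#
# Two artificial reef systems with known generative parameters let every
# downstream stage (scenario construction, model fitting, selection,
# validation, transfer) be tested against recorded truth without external
# survey data.

#' Configure a synthetic reef system
#'
#' Describes one reef system: its survey design (reefs, sites, transects,
#' years), its spatial extent, the environmental covariates available on its
#' predictor grid, and the generative count model. Site-level expected counts
#' follow `mu = exp(X beta + alpha_reef)` with `alpha_reef ~ N(0, sigma_alpha^2)`,
#' site counts are NB2 draws (`variance = mu + mu^2 / theta`), and each site
#' count is split across transects by an equal-probability multinomial.
#'
#' `beta` is a named vector on the log scale. Names must be `"(Intercept)"`,
#' covariate names from `covariate_ranges`, or `<covariate>_sq` for quadratic
#' terms. Covariates enter the linear predictor centred at the midpoint of
#' their configured range so that realistic covariate units do not blow up the
#' exponential; quadratic terms are squares of the midpoint-centred values.
#'
#' @param system_id Label for the system.
#' @param n_reefs,sites_per_reef,transects_per_site Survey design counts.
#' @param transect_length_m Transect length in metres (50 or 25 in the two
#'   systems emulated here).
#' @param years Integer vector of survey years.
#' @param beta Named numeric vector of fixed effects on the log scale,
#'   including `"(Intercept)"`.
#' @param sigma_alpha Standard deviation of reef-level random intercepts
#'   (log scale), `>= 0`.
#' @param theta NB2 dispersion (`> 0`); a single value, or a named vector with
#'   one entry per family when `families` is given.
#' @param covariate_ranges Named list of `c(min, max)` pairs, one per
#'   covariate carried on the predictor grid.
#' @param families Optional named numeric vector of relative abundance shares
#'   per fish family (multipliers of `mu`). When given, counts are generated
#'   per family and `TOTAL` rows are their sums.
#' @param lon_range,lat_range Spatial extent of the system in decimal degrees.
#' @param site_sd Standard deviation (degrees) of the Gaussian scatter of
#'   sites around their reef centroid.
#' @param grid_step Predictor-grid node spacing in degrees.
#' @param seed Integer seed; all randomness in [generate_system()] flows from
#'   it and global random state is left untouched.
#' @return An object of class `system_config` (a named list).
#' @seealso [generate_system()], [make_target_system()]
#' @export
system_config <- function(system_id = "REF",
                          n_reefs = 46,
                          sites_per_reef = 3,
                          transects_per_site = 5,
                          transect_length_m = 50,
                          years = c(2003, 2004, 2005, 2007, 2009, 2011, 2013),
                          beta = default_beta(),
                          sigma_alpha = 0.5,
                          theta = 5,
                          covariate_ranges = default_covariate_ranges(),
                          families = NULL,
                          lon_range = c(145, 150),
                          lat_range = c(-20, -15),
                          site_sd = 0.02,
                          grid_step = 0.05,
                          seed = 1L) {
  stopifnot(
    n_reefs >= 1, sites_per_reef >= 1, transects_per_site >= 1,
    all(theta > 0), sigma_alpha >= 0, length(years) >= 1
  )
  ok <- vapply(covariate_ranges, function(r) {
    length(r) == 2 && all(is.finite(r)) && r[1] < r[2]
  }, logical(1))
  if (!all(ok)) {
    abort(paste0("invalid covariate range(s): ",
                 paste(names(covariate_ranges)[!ok], collapse = ", ")))
  }
  if (is.null(names(beta)) || !"(Intercept)" %in% names(beta)) {
    abort("`beta` must be named and include \"(Intercept)\"")
  }
  extra <- setdiff(base_name(setdiff(names(beta), "(Intercept)")),
                   names(covariate_ranges))
  if (length(extra) > 0) {
    abort(paste0("beta names not in covariate_ranges: ",
                 paste(extra, collapse = ", ")))
  }
  if (!is.null(families)) {
    stopifnot(!is.null(names(families)), all(families > 0))
    if (length(theta) > 1) stopifnot(setequal(names(theta), names(families)))
  }
  structure(
    list(
      system_id = system_id, n_reefs = n_reefs,
      sites_per_reef = sites_per_reef,
      transects_per_site = transects_per_site,
      transect_length_m = transect_length_m, years = as.integer(years),
      beta = beta, sigma_alpha = sigma_alpha, theta = theta,
      covariate_ranges = covariate_ranges, families = families,
      lon_range = lon_range, lat_range = lat_range, site_sd = site_sd,
      grid_step = grid_step, seed = as.integer(seed)
    ),
    class = "system_config"
  )
}

#' @export
print.system_config <- function(x, ...) {
  cat("<system_config> ", x$system_id, ": ", x$n_reefs, " reefs x ",
      x$sites_per_reef, " sites x ", x$transects_per_site, " transects (",
      x$transect_length_m, " m), years ", paste(range(x$years), collapse = "-"),
      "\n", sep = "")
  cat("  covariates: ", paste(names(x$covariate_ranges), collapse = ", "),
      "\n", sep = "")
  cat("  sigma_alpha = ", x$sigma_alpha, ", theta = ",
      paste(x$theta, collapse = "/"), ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Default generative coefficients for the synthetic reference system
#'
#' Intercept `log(300)` plus moderate effects of nitrate, temperature (with a
#' concave quadratic), and distance to coast: the kind of smooth broad-scale
#' structure the candidate model set is designed to detect.
#'
#' @return Named numeric vector on the log scale.
#' @export
default_beta <- function() {
  c(`(Intercept)` = log(300),
    no3_av = 0.8, sst_av = 0.15, sst_av_sq = -0.08, coast = -0.02)
}

#' Default covariate ranges for the synthetic systems
#'
#' Plausible magnitudes for the broad-scale predictors used by the candidate
#' model set: temperature (deg C), nutrients (umol/L), oxygen (mL/L),
#' salinity (PSU), chlorophyll-a (mg/m3), light attenuation (1/m), depth (m),
#' slope (deg), sediment fractions (%), and distances to the coast and the
#' outer reef barrier (km).
#'
#' @return Named list of `c(min, max)` pairs.
#' @export
default_covariate_ranges <- function() {
  list(
    sst_av = c(24, 29), no3_av = c(0.05, 0.6), po4_av = c(0.05, 0.3),
    si_av = c(1, 4), o2_av = c(4.2, 4.9), sal_av = c(34.5, 35.8),
    chla_av = c(0.1, 0.8), k490_av = c(0.02, 0.12),
    depth = c(-40, -2), slope = c(0, 12),
    crbnt = c(60, 95), gravel = c(0, 30), sand = c(20, 70), mud = c(0, 25),
    coast = c(5, 120), barrier = c(1, 60)
  )
}

# Smooth spatial field on [0,1]^2: a random linear gradient plus two
# low-frequency sinusoids. Deterministic given the prevailing RNG state.
smooth_field <- function() {
  w <- rnorm(2)
  a <- runif(2, 0.5, 2)
  ph <- runif(2, 0, 2 * pi)
  amp <- runif(1, 0.2, 0.5)
  function(u, v) {
    w[1] * u + w[2] * v +
      amp * sin(2 * pi * a[1] * u + ph[1]) +
      amp * sin(2 * pi * a[2] * v + ph[2])
  }
}

#' Generate a synthetic reef system
#'
#' Draws reef centroids and Gaussian site clusters inside the system extent,
#' builds a regular predictor grid whose covariates are smooth spatial fields
#' rescaled to the configured ranges, assigns each site the covariates of its
#' nearest grid node, and generates transect-level NB2 counts for every survey
#' year. The generative truth (coefficients, random intercepts, dispersion,
#' the site-level design and expected counts) is returned for recovery tests.
#'
#' @param config A [system_config()].
#' @return A list of class `synthetic_system` with elements
#'   * `survey`: tibble of transect-level counts
#'     (system_id, reef_id, site_id, latitude, longitude, year, transect_id,
#'     family, count) — the survey table consumed by [pool_transects_to_site()]
#'     and [build_scenario()];
#'   * `grid`: tibble predictor grid (node_id, longitude, latitude,
#'     covariates);
#'   * `sites`: tibble of site coordinates and their assigned node and
#'     covariate values;
#'   * `truth`: list with `beta`, `sigma_alpha`, `theta`, `alpha` (per reef),
#'     `mu` (per site and family), `centers` (range midpoints used in the
#'     linear predictor), and `config`.
#' @export
generate_system <- function(config) {
  stopifnot(inherits(config, "system_config"))
  withr::with_seed(config$seed, generate_system_impl(config))
}

generate_system_impl <- function(cfg) {
  n_sites <- cfg$n_reefs * cfg$sites_per_reef

  reef_ids <- sprintf("%s_R%02d", cfg$system_id, seq_len(cfg$n_reefs))
  reef_lon <- runif(cfg$n_reefs, cfg$lon_range[1], cfg$lon_range[2])
  reef_lat <- runif(cfg$n_reefs, cfg$lat_range[1], cfg$lat_range[2])

  sites <- tibble::tibble(
    system_id = cfg$system_id,
    reef_id = rep(reef_ids, each = cfg$sites_per_reef),
    site_id = sprintf("%s_S%03d", cfg$system_id, seq_len(n_sites)),
    longitude = rep(reef_lon, each = cfg$sites_per_reef) +
      rnorm(n_sites, 0, cfg$site_sd),
    latitude = rep(reef_lat, each = cfg$sites_per_reef) +
      rnorm(n_sites, 0, cfg$site_sd)
  )

  # Predictor grid: regular lattice over the extent, covariates as smooth
  # fields rescaled into the configured ranges.
  lon_nodes <- seq(cfg$lon_range[1], cfg$lon_range[2], by = cfg$grid_step)
  lat_nodes <- seq(cfg$lat_range[1], cfg$lat_range[2], by = cfg$grid_step)
  grid <- tidyr::expand_grid(longitude = lon_nodes, latitude = lat_nodes)
  grid <- tibble::tibble(node_id = seq_len(nrow(grid)), grid)
  u_g <- (grid$longitude - cfg$lon_range[1]) / diff(cfg$lon_range)
  v_g <- (grid$latitude - cfg$lat_range[1]) / diff(cfg$lat_range)
  for (cov in names(cfg$covariate_ranges)) {
    f <- smooth_field()
    raw <- f(u_g, v_g)
    rng <- cfg$covariate_ranges[[cov]]
    grid[[cov]] <- rng[1] + (raw - min(raw)) / (max(raw) - min(raw)) *
      (rng[2] - rng[1])
  }

  # Sites take the covariates of their nearest grid node, so the pipeline's
  # nearest-node assignment recovers the generative covariates exactly.
  assign <- nearest_node_assign(sites, grid)
  sites <- dplyr::left_join(
    dplyr::mutate(sites, node_id = assign$node_id),
    dplyr::select(grid, -"longitude", -"latitude"),
    by = "node_id"
  )

  # Linear predictor on midpoint-centred covariates.
  centers <- vapply(cfg$covariate_ranges, mean, numeric(1))
  eta <- rep(cfg$beta[["(Intercept)"]], n_sites)
  contrib <- matrix(0, n_sites, length(cfg$beta),
                    dimnames = list(NULL, names(cfg$beta)))
  contrib[, "(Intercept)"] <- cfg$beta[["(Intercept)"]]
  for (term in setdiff(names(cfg$beta), "(Intercept)")) {
    cov <- base_name(term)
    x <- sites[[cov]] - centers[[cov]]
    if (is_sq_name(term)) x <- x^2
    contrib[, term] <- cfg$beta[[term]] * x
    eta <- eta + contrib[, term]
  }

  alpha <- rnorm(cfg$n_reefs, 0, cfg$sigma_alpha)
  names(alpha) <- reef_ids
  eta <- eta + alpha[sites$reef_id]
  mu <- exp(eta)
  if (any(!is.finite(mu))) {
    bad <- which(!is.finite(mu))[1]
    worst <- names(cfg$beta)[which.max(abs(contrib[bad, ]))]
    abort(paste0("non-finite expected count at site ", sites$site_id[bad],
                 "; largest linear-predictor contribution from coefficient '",
                 worst, "'"))
  }

  families <- cfg$families %||% c(TOTAL = 1)
  theta <- cfg$theta
  if (length(theta) == 1) theta <- setNames(rep(theta, length(families)),
                                            names(families))

  # Per family: NB2 site-year counts, multinomially split over transects.
  blocks <- list()
  mu_truth <- list()
  draws <- list()
  for (fam in names(families)) {
    mu_f <- mu * families[[fam]]
    mu_truth[[fam]] <- mu_f
    for (yr in cfg$years) {
      site_counts <- rnbinom(n_sites, mu = mu_f, size = theta[[fam]])
      draws[[length(draws) + 1]] <- tibble::tibble(
        site_id = sites$site_id, year = yr, family = fam,
        site_count = as.integer(site_counts)
      )
      split <- vapply(site_counts, function(n) {
        rmultinom(1, n, rep(1, cfg$transects_per_site))[, 1]
      }, integer(cfg$transects_per_site))
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        system_id = cfg$system_id,
        reef_id = rep(sites$reef_id, each = cfg$transects_per_site),
        site_id = rep(sites$site_id, each = cfg$transects_per_site),
        latitude = rep(sites$latitude, each = cfg$transects_per_site),
        longitude = rep(sites$longitude, each = cfg$transects_per_site),
        year = yr,
        transect_id = rep(seq_len(cfg$transects_per_site), n_sites),
        family = fam,
        count = as.integer(split)
      )
    }
  }
  survey <- dplyr::bind_rows(blocks)

  # TOTAL rows are the per-transect sum over families (identically zero work
  # when only TOTAL was generated).
  if (!is.null(cfg$families)) {
    totals <- survey |>
      dplyr::summarise(
        count = sum(.data$count),
        .by = c("system_id", "reef_id", "site_id", "latitude", "longitude",
                "year", "transect_id")
      ) |>
      dplyr::mutate(family = "TOTAL", .before = "count")
    survey <- dplyr::bind_rows(survey, totals)
  }
  survey <- dplyr::arrange(survey, .data$site_id, .data$year, .data$family,
                           .data$transect_id)

  structure(
    list(
      survey = survey, grid = grid, sites = sites,
      truth = list(beta = cfg$beta, sigma_alpha = cfg$sigma_alpha,
                   theta = theta, alpha = alpha, mu = mu_truth,
                   site_counts = dplyr::bind_rows(draws),
                   centers = centers, config = cfg)
    ),
    class = "synthetic_system"
  )
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat("<synthetic_system> ", x$truth$config$system_id, ": ",
      nrow(x$sites), " sites, ", nrow(x$grid), " grid nodes, ",
      nrow(x$survey), " survey rows\n", sep = "")
  invisible(x)
}

#' Derive a target-system configuration with shifted covariate ranges
#'
#' Model transfer between reef systems typically faces covariate ranges that
#' only partially overlap: part of the target system's environmental space was
#' never seen during calibration, and predictions there must be clipped. This
#' helper shifts selected covariate ranges of a reference configuration by
#' fixed offsets so a controlled fraction of each target range lies outside
#' the reference range.
#'
#' @param config A [system_config()] for the reference system.
#' @param range_shift Named numeric vector of offsets (same units as each
#'   covariate); covariates not named are left unchanged.
#' @param system_id,seed Identity of the new system (default: `"TGT"`,
#'   `config$seed + 1`).
#' @param ... Further `system_config` fields to override (e.g. `n_reefs`,
#'   `years`, `transect_length_m`, `lon_range`).
#' @return A new `system_config`.
#' @export
make_target_system <- function(config, range_shift = numeric(),
                               system_id = "TGT", seed = config$seed + 1L,
                               ...) {
  stopifnot(inherits(config, "system_config"))
  if (length(range_shift) > 0) {
    stopifnot(!is.null(names(range_shift)), all(is.finite(range_shift)))
    unknown <- setdiff(names(range_shift), names(config$covariate_ranges))
    if (length(unknown) > 0) {
      abort(paste0("range_shift names not in covariate_ranges: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  fields <- unclass(config)
  for (cov in names(range_shift)) {
    fields$covariate_ranges[[cov]] <-
      fields$covariate_ranges[[cov]] + range_shift[[cov]]
  }
  fields$system_id <- system_id
  fields$seed <- as.integer(seed)
  dots <- list(...)
  fields[names(dots)] <- dots
  do.call(system_config, fields)
}

#' Fractional overlap of covariate ranges between two system configurations
#'
#' For each covariate, the length of the intersection of the two configured
#' ranges divided by the length of the *target* range: the fraction of the
#' target system's environmental space that lies inside the reference
#' calibration range.
#'
#' @param reference,target `system_config` objects.
#' @return Tibble with columns `covariate`, `overlap` (in `[0, 1]`).
#' @export
covariate_overlap <- function(reference, target) {
  covs <- intersect(names(reference$covariate_ranges),
                    names(target$covariate_ranges))
  overlap <- vapply(covs, function(cov) {
    r <- reference$covariate_ranges[[cov]]
    t <- target$covariate_ranges[[cov]]
    max(0, min(r[2], t[2]) - max(r[1], t[1])) / (t[2] - t[1])
  }, numeric(1))
  tibble::tibble(covariate = covs, overlap = unname(overlap))
}

#' Write a synthetic system to plain-text files
#'
#' Survey table and predictor grid as UTF-8 CSV, generative truth as JSON.
#'
#' @param system A `synthetic_system`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_system <- function(system, dir) {
  stopifnot(inherits(system, "synthetic_system"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- system$truth$config$system_id
  paths <- c(
    survey = file.path(dir, paste0(id, "_survey.csv")),
    grid = file.path(dir, paste0(id, "_grid.csv")),
    truth = file.path(dir, paste0(id, "_truth.json"))
  )
  utils::write.csv(system$survey, paths[["survey"]], row.names = FALSE)
  utils::write.csv(system$grid, paths[["grid"]], row.names = FALSE)
  truth <- system$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
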