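# Scenario construction: transect pooling, year windows, and the randomized
# transect-downscaling algorithm.

#' The seven scenario definitions
#'
#' Each scenario selects a year window from the reference system's survey
#' series and optionally downscales transect counts to the target system's
#' shorter transect length before pooling: A = 2003-2007 raw, B = 2007-2013
#' raw, C = 2007-2013 downscaled, D = 2007 raw, E = 2007 downscaled,
#' F = 2013 downscaled, G = 2013 raw.
#'
#' @return Tibble with columns `scenario_id`, `years` (list column of year
#'   windows), `downscaled`.
#' @export
scenario_specs <- function() {
  tibble::tibble(
    scenario_id = LETTERS[1:7],
    years = list(2003:2007, 2007:2013, 2007:2013, 2007L, 2007L, 2013L, 2013L),
    downscaled = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
}

#' Pool transect counts to site level
#'
#' Sums counts across the transects of each site, per year and family, the
#' unit at which the abundance models are fitted. `family = "TOTAL"` uses the
#' survey's TOTAL rows when present and otherwise sums across all families.
#'
#' @param survey Survey tibble with columns `system_id`, `reef_id`, `site_id`,
#'   `latitude`, `longitude`, `year`, `transect_id`, `family`, `count`.
#' @param family Family label to pool, or `"TOTAL"`.
#' @param n_expected Declared number of transects per site, if known; sites
#'   with fewer observed transects trigger a warning naming them, and pooling
#'   proceeds on the available transects.
#' @param statistic `"sum"` (default; total individuals over the site's
#'   swept area) or `"mean"` (per-transect density). Whether densities are
#'   summed or averaged across transects is a reporting convention; the sum
#'   is used throughout this package.
#' @return Tibble with one row per (site, year): keys, `pooled_count`,
#'   `n_transects_pooled`.
#' @export
pool_transects_to_site <- function(survey, family = "TOTAL",
                                   n_expected = NULL,
                                   statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(all(survey$count >= 0))
  if (family == "TOTAL" && !"TOTAL" %in% survey$family) {
    rows <- survey |>
      dplyr::summarise(
        count = sum(.data$count),
        .by = c("system_id", "reef_id", "site_id", "latitude", "longitude",
                "year", "transect_id")
      )
  } else {
    rows <- dplyr::filter(survey, .data$family == !!family)
    if (nrow(rows) == 0) {
      abort(paste0("no survey rows for family '", family, "'"))
    }
  }
  agg <- if (statistic == "sum") sum else function(x) mean(x)
  pooled <- rows |>
    dplyr::summarise(
      pooled_count = agg(.data$count),
      n_transects_pooled = dplyr::n(),
      .by = c("system_id", "reef_id", "site_id", "latitude", "longitude",
              "year")
    )
  if (!is.null(n_expected)) {
    short <- pooled$site_id[pooled$n_transects_pooled < n_expected]
    if (length(short) > 0) {
      warn(paste0("fewer than ", n_expected, " transects at site(s): ",
                  paste(unique(short), collapse = ", ")))
    }
  }
  pooled
}

#' Average increase in abundance per added transect
#'
#' Within one site, the cumulative count grows as transects are added one at a
#' time. The average increment per added transect is estimated by randomising
#' the order in which transects are added and averaging the step increments
#' over all permutations and steps. Because the cumulative sum telescopes,
#' every single ordering already has mean step increment `sum(x) / length(x)`,
#' so the randomized estimate equals the analytic site mean exactly; both are
#' returned and compared.
#'
#' @param transect_counts Numeric vector of one site's transect counts
#'   (length `>= 2`).
#' @param n_permutations Number of random orderings (default 999).
#' @param seed Integer seed for the permutations.
#' @return List with `randomized`, `analytic` (the site mean), and
#'   `n_permutations`.
#' @export
estimate_transect_increment <- function(transect_counts, n_permutations = 999,
                                        seed = 1L) {
  n <- length(transect_counts)
  if (n < 2) abort("at least 2 transects are required to estimate increments")
  increments <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      ord <- sample.int(n)
      mean(diff(c(0, cumsum(transect_counts[ord]))))
    }, numeric(1))
  })
  list(
    randomized = mean(increments),
    analytic = sum(transect_counts) / n,
    n_permutations = n_permutations
  )
}

#' Downscale transect counts to a shorter transect length
#'
#' Converts counts observed on long transects to their expected value on
#' transects shorter by `length_ratio` (50 m to 25 m gives ratio 2), by
#' subtracting from each transect the site's average per-transect increment
#' divided by the ratio: `count - (average increase / length_ratio)`. Values
#' are floored at zero (below-average transects can otherwise go negative)
#' and, by default, integerized half-up. The procedure uses only the site's
#' own transects: no information is shared beyond the reef scale.
#'
#' @param transect_counts Numeric vector of one site's transect counts
#'   (length `>= 2`).
#' @param length_ratio Positive divisor: reference transect length over target
#'   transect length (default 2).
#' @param round Integerize the result half-up (default `TRUE`). The scenario
#'   builder postpones integerization to its final step.
#' @return Numeric vector of downscaled counts, same length as the input.
#' @export
#' @examples
#' downscale_counts(c(10, 20, 30))  # average increase 20 -> c(0, 10, 20)
downscale_counts <- function(transect_counts, length_ratio = 2,
                             round = TRUE) {
  if (length_ratio <= 0) abort("`length_ratio` must be positive")
  if (length(transect_counts) < 2) {
    abort("at least 2 transects are required to downscale")
  }
  avg_increase <- sum(transect_counts) / length(transect_counts)
  out <- pmax(0, transect_counts - avg_increase / length_ratio)
  if (round) out <- round_half_up(out)
  out
}

#' Build one scenario dataset of site-level counts
#'
#' Restricts the survey to the scenario's year window, optionally downscales
#' transect counts (per site and year) before pooling, pools transects to
#' sites, and for multi-year windows averages the per-site counts across years.
#' The across-year mean is integerized half-up in a single final step, since
#' the count likelihood requires integers.
#'
#' @param survey Survey tibble (see [pool_transects_to_site()]).
#' @param scenario_id One of `"A"`-`"G"`, or a one-row tibble shaped like
#'   [scenario_specs()] for custom windows.
#' @param family Family label or `"TOTAL"`.
#' @param length_ratio Transect-length ratio used when the scenario is
#'   downscaled (default 2).
#' @return Tibble with one row per site: keys, coordinates, `scenario_id`,
#'   `family`, `pooled_count` (integer), `n_transects_pooled`, `n_years`.
#' @export
build_scenario <- function(survey, scenario_id, family = "TOTAL",
                           length_ratio = 2) {
  if (is.character(scenario_id)) {
    spec <- dplyr::filter(scenario_specs(), .data$scenario_id == !!scenario_id)
    if (nrow(spec) == 0) abort(paste0("unknown scenario '", scenario_id, "'"))
  } else {
    spec <- scenario_id
  }
  years <- spec$years[[1]]
  sub <- dplyr::filter(survey, .data$year %in% years)
  if (nrow(sub) == 0) {
    abort(paste0("scenario ", spec$scenario_id,
                 ": no survey rows in years ",
                 paste(range(years), collapse = "-")))
  }
  if (spec$downscaled) {
    fam_rows <- if (family == "TOTAL" && !"TOTAL" %in% sub$family) {
      sub |>
        dplyr::summarise(count = sum(.data$count),
                         .by = c("system_id", "reef_id", "site_id", "latitude",
                                 "longitude", "year", "transect_id"))
    } else {
      dplyr::filter(sub, .data$family == !!family)
    }
    if (nrow(fam_rows) == 0) {
      abort(paste0("no survey rows for family '", family, "'"))
    }
    fam_rows <- fam_rows |>
      dplyr::mutate(
        count = downscale_counts(.data$count, length_ratio, round = FALSE),
        .by = c("site_id", "year")
      )
    pooled <- fam_rows |>
      dplyr::summarise(
        pooled_count = sum(.data$count),
        n_transects_pooled = dplyr::n(),
        .by = c("system_id", "reef_id", "site_id", "latitude", "longitude",
                "year")
      )
  } else {
    pooled <- pool_transects_to_site(sub, family = family)
  }
  pooled |>
    dplyr::summarise(
      pooled_count = round_half_up(mean(.data$pooled_count)),
      n_transects_pooled = max(.data$n_transects_pooled),
      n_years = dplyr::n(),
      .by = c("system_id", "reef_id", "site_id", "latitude", "longitude")
    ) |>
    dplyr::mutate(scenario_id = spec$scenario_id, family = family,
                  .after = "site_id")
}
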