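# Shared fixtures, built in code at test time.

# A small twin-system pair: reference with the full survey series, target with
# a single year, shorter transects and a shifted temperature range.
small_ref_config <- function(seed = 101L, ...) {
  system_config(system_id = "REF", n_reefs = 10, sites_per_reef = 3,
                grid_step = 0.25, seed = seed, ...)
}

small_target_config <- function(ref = small_ref_config(), seed = 202L) {
  make_target_system(ref, range_shift = c(sst_av = 2), system_id = "TGT",
                     seed = seed, n_reefs = 8, transects_per_site = 3,
                     transect_length_m = 25, years = 2013L,
                     lon_range = c(113, 115), lat_range = c(-23, -21))
}

# Scenario data joined to its grid covariates: the model-ready table.
model_data_for <- function(system, scenario = "G", family = "TOTAL") {
  samples <- build_scenario(system$survey, scenario, family = family)
  assign <- nearest_node_assign(samples, system$grid)
  dplyr::bind_cols(
    samples,
    dplyr::select(
      dplyr::left_join(assign["node_id"], system$grid, by = "node_id"),
      -"longitude", -"latitude"
    )
  )
}

all_predictors <- function() {
  unique(sub("_sq$", "", unlist(model_set("GBR")$terms)))
}

# A tiny handmade survey table: 1 site, 5 transects, 2 years, 2 families.
toy_survey <- function() {
  tidyr::expand_grid(year = c(2007L, 2013L), transect_id = 1:5,
                     family = c("Acanthuridae", "Pomacentridae")) |>
    dplyr::mutate(
      system_id = "TOY", reef_id = "TOY_R1", site_id = "TOY_S1",
      latitude = -18, longitude = 147,
      count = dplyr::case_when(
        family == "Acanthuridae" & year == 2007L ~
          c(10L, 20L, 30L, 5L, 15L)[transect_id],
        family == "Acanthuridae" & year == 2013L ~
          c(8L, 8L, 8L, 8L, 8L)[transect_id],
        family == "Pomacentridae" & year == 2007L ~
          c(1L, 2L, 3L, 4L, 5L)[transect_id],
        .default = 2L
      )
    )
}

# Minimal prediction grids for metric arithmetic.
pgrid <- function(fit, clipped = FALSE, node_id = seq_along(fit)) {
  out <- tibble::tibble(
    node_id = node_id,
    longitude = node_id * 0.01, latitude = -18 + node_id * 0.01,
    fit = fit, se = 0.1, clipped = clipped
  )
  out$fit[out$clipped] <- NA_real_
  class(out) <- c("prediction_grid", class(out))
  out
}
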