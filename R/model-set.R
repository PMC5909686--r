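# The fixed candidate set of abundance models.

#' The candidate model set
#'
#' Twelve models relating fish abundance to spatial and environmental
#' properties, fitted identically for every scenario and response: a full
#' model, distances to domain boundaries, physical predictors, three
#' single-sediment models (sediment fractions are mutually collinear and are
#' never mixed), nutrients, oxygen/salinity, productivity, temperature, light,
#' and an intercept-only null (model 12). `coast`, `barrier`, `depth` and
#' `sst_av` enter as second-order polynomials on centred values.
#'
#' Editions differ by system: the `"NR"` edition omits nitrate from the full
#' model and carbonate from the sediment model (collinear in that system), and
#' `"NR+rugosity"` appends model 13, a quadratic in transect rugosity, the
#' local topographic add-on available only there.
#'
#' @param edition `"GBR"`, `"NR"`, or `"NR+rugosity"`.
#' @return Tibble with `model_id`, `category`, `terms` (list column of design
#'   column names; `character(0)` for the null model).
#' @export
model_set <- function(edition = c("GBR", "NR", "NR+rugosity")) {
  edition <- match.arg(edition)
  full <- c("coast", "coast_sq", "barrier", "barrier_sq", "slope", "no3_av")
  sediment4 <- c("crbnt", "gravel")
  if (edition != "GBR") {
    full <- setdiff(full, "no3_av")
    sediment4 <- "gravel"
  }
  set <- tibble::tibble(
    model_id = 1:12,
    category = c("Full model", "Distance to domain boundaries",
                 "Physical predictors", "Sediment characteristics",
                 "Sediment characteristics", "Sediment characteristics",
                 "Nutrients", "Oxygen and salinity", "Productivity",
                 "Temperature", "Light availability", "Null model"),
    terms = list(
      full,
      c("coast", "coast_sq", "barrier", "barrier_sq"),
      c("depth", "depth_sq", "slope"),
      sediment4,
      "sand",
      "mud",
      c("no3_av", "po4_av", "si_av"),
      c("o2_av", "sal_av"),
      "chla_av",
      c("sst_av", "sst_av_sq"),
      "k490_av",
      character(0)
    )
  )
  if (edition == "NR+rugosity") {
    set <- dplyr::bind_rows(set, tibble::tibble(
      model_id = 13L, category = "Rugosity",
      terms = list(c("rugosity", "rugosity_sq"))
    ))
  }
  set
}
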