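# End-to-end orchestration: reference runs (scenario x response model
# selection, validation, grid prediction) and transfer runs between systems.

edition_predictors <- function(edition, available) {
  wanted <- unique(base_name(unlist(model_set(edition)$terms)))
  missing_p <- setdiff(wanted, available)
  if (length(missing_p) > 0) {
    abort(paste0("predictor grid lacks column(s) required by the ", edition,
                 " model set: ", paste(missing_p, collapse = ", ")))
  }
  wanted
}

QUADRATIC_PREDICTORS <- c("coast", "barrier", "depth", "sst_av", "rugosity")

#' Run the reference analysis for one system
#'
#' For every scenario and response: builds the scenario dataset, assigns
#' sites to predictor-grid nodes, centres and expands the predictors, fits
#' the full candidate model set (GLMM with a reef random intercept by
#' default, GLM when `group = NULL`), ranks by AICc weight, computes effect
#' sizes, cross-validates the top model, validates model-averaged in-sample
#' predictions directly against observations, predicts the full grid with
#' calibration clipping, and computes a residual Moran's I correlogram for
#' the top model.
#'
#' @param survey Transect-level survey tibble (see [generate_system()]).
#' @param grid Predictor-grid tibble (`node_id`, coordinates, predictors).
#' @param scenarios Scenario table as from [scenario_specs()]; subset rows to
#'   run fewer scenarios.
#' @param responses Character vector of responses (`"TOTAL"` and/or family
#'   labels).
#' @param edition Model-set edition (see [model_set()]).
#' @param group Grouping column for the random intercept, or `NULL` for
#'   GLMs.
#' @param k Cross-validation folds.
#' @param seed Integer seed for fold assignment (one deterministic stream per
#'   scenario x response, derived by offset).
#' @param length_ratio Transect-length ratio for downscaled scenarios.
#' @return A `reference_run`: list with `summary` (one row per scenario x
#'   response, mirroring the reference reporting tables) and `details` (per
#'   combination: ranked set, predictor set, raw model data, CV result,
#'   prediction grid, correlogram).
#' @export
run_reference <- function(survey, grid, scenarios = scenario_specs(),
                          responses = "TOTAL", edition = "GBR",
                          group = "reef_id", k = 10, seed = 1L,
                          length_ratio = 2) {
  predictors <- edition_predictors(edition, names(grid))
  set <- model_set(edition)
  details <- list()
  summary_rows <- list()
  task <- 0L
  for (sc in seq_len(nrow(scenarios))) {
    for (resp in responses) {
      task <- task + 1L
      spec <- scenarios[sc, ]
      samples <- build_scenario(survey, spec, family = resp,
                                length_ratio = length_ratio)
      assign <- nearest_node_assign(samples, grid)
      model_data <- dplyr::bind_cols(
        samples,
        dplyr::select(
          dplyr::left_join(assign["node_id"], grid, by = "node_id"),
          -"longitude", -"latitude"
        )
      )
      pset <- build_predictor_set(model_data, predictors,
                                  quadratic = QUADRATIC_PREDICTORS)
      fits <- purrr::map(seq_len(nrow(set)), function(i) {
        terms <- set$terms[[i]]
        if (is.null(group)) {
          fit_nb_glm(pset$data, terms, model_id = set$model_id[i])
        } else {
          fit_nb_glmm(pset$data, terms, group = group,
                      model_id = set$model_id[i])
        }
      })
      ranked <- waicc_rank(fits)
      es <- effect_sizes(ranked)
      top_fit <- attr(ranked, "fits")[[1]]
      cv <- kfold_cv(pset$data, top_fit$terms, group = group, k = k,
                     seed = seed + task)
      avg_pred <- model_average_predictions(ranked, pset$data)
      val <- direct_validation(pset$data$pooled_count, avg_pred$fit)
      grid_pset <- build_predictor_set(grid, predictors,
                                       quadratic = QUADRATIC_PREDICTORS,
                                       centers = pset$centers)
      grid_pred <- predict_grid_clipped(ranked, grid_pset, pset)
      corr <- moran_correlogram(
        residuals(top_fit, type = "deviance"),
        samples[, c("longitude", "latitude")]
      )
      key <- paste0(spec$scenario_id, "_", resp)
      details[[key]] <- list(
        scenario_id = spec$scenario_id, response = resp, ranked = ranked,
        pset = pset, model_data = model_data, effect_sizes = es, cv = cv,
        grid_pred = grid_pred, correlogram = corr
      )
      unclipped <- grid_pred$fit[!grid_pred$clipped]
      summary_rows[[key]] <- tibble::tibble(
        scenario_id = spec$scenario_id, response = resp,
        n_sites = nrow(samples),
        obs_min = min(samples$pooled_count),
        obs_max = max(samples$pooled_count),
        top_model = ranked$model_id[1], waicc = ranked$waicc[1],
        r2m_pct = 100 * ranked$r2m[1], r2c_pct = 100 * ranked$r2c[1],
        de_pct = ranked$de_pct[1],
        highest_effect = es$predictor[1],
        pred_min = if (length(unclipped)) min(unclipped) else NA_real_,
        pred_max = if (length(unclipped)) max(unclipped) else NA_real_,
        cv_error = cv$error_mean, cv_error_sd = cv$error_sd,
        cv_pct = cv$pct_mean, cv_pct_sd = cv$pct_sd,
        val_r2_pct = val$r2_pct, val_p = val$p_value,
        null_support = null_support(ranked),
        first_lag_moran = first_lag_moran(corr)
      )
    }
  }
  structure(
    list(summary = dplyr::bind_rows(summary_rows), details = details,
         edition = edition, group = group, predictors = predictors,
         grid = grid, seed = seed,
         hash = rlang::hash(list(scenarios, responses, edition, group, k,
                                 seed))),
    class = "reference_run"
  )
}

#' @export
print.reference_run <- function(x, ...) {
  cat("<reference_run> ", x$edition, " edition, ",
      nrow(x$summary), " scenario x response combination(s), seed ",
      x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Transfer reference-system models to a target system
#'
#' Applies each reference scenario's fitted candidate set (model-averaged, or
#' the single top model) to the target system's predictor grid — with the
#' target's predictors centred by the *reference* system's constants and
#' clipped to the reference calibration ranges — and assembles the four-part
#' transferability report against the target system's own reference
#' predictions. Transferred predictions at the target's surveyed sites are
#' validated directly against the target observations.
#'
#' Rows are flagged `included` when they meet the default reporting filter:
#' the reference fit validated significantly in its own system and the null
#' model's weight is at most `null_cutoff`.
#'
#' @param reference_run A `reference_run` for the reference system.
#' @param target_run A `reference_run` for the target system (its grid and
#'   observations are the comparison baseline). Responses are matched by
#'   name; the target run's first scenario per response is used.
#' @param use `"averaged"` (default) or `"top"`: transfer the model-averaged
#'   set or the single best model.
#' @param tolerance Relative tolerance for the within-tolerance metric.
#' @param null_cutoff Null-model weight cutoff for the `included` flag
#'   (default 0.1).
#' @return A `transfer_run`: list with `summary` (one `transfer_report` row
#'   per reference scenario x response) and `grids` (transferred prediction
#'   grids).
#' @export
run_transfer <- function(reference_run, target_run,
                         use = c("averaged", "top"), tolerance = 0.15,
                         null_cutoff = 0.1) {
  use <- match.arg(use)
  stopifnot(inherits(reference_run, "reference_run"),
            inherits(target_run, "reference_run"))
  target_grid <- target_run$grid
  rows <- list()
  grids <- list()
  for (key in names(reference_run$details)) {
    ref <- reference_run$details[[key]]
    t_keys <- names(target_run$details)[
      vapply(target_run$details, function(d) d$response == ref$response,
             logical(1))
    ]
    if (length(t_keys) == 0) next
    tgt <- target_run$details[[t_keys[1]]]
    predictors <- intersect(reference_run$predictors,
                            names(target_grid))
    t_grid_pset <- build_predictor_set(
      target_grid, predictors, quadratic = QUADRATIC_PREDICTORS,
      centers = ref$pset$centers
    )
    t_site_pset <- build_predictor_set(
      tgt$model_data, predictors, quadratic = QUADRATIC_PREDICTORS,
      centers = ref$pset$centers
    )
    model <- if (use == "averaged") ref$ranked else
      attr(ref$ranked, "fits")[[1]]
    transferred <- predict_grid_clipped(model, t_grid_pset, ref$pset)
    pred_sites <- if (use == "averaged") {
      model_average_predictions(ref$ranked, t_site_pset$data)
    } else {
      predict_response(model, t_site_pset$data, mode = "population")
    }
    report <- transfer_report(
      transferred, tgt$grid_pred,
      observed = tgt$model_data$pooled_count,
      predicted_at_sites = pred_sites$fit,
      tolerance = tolerance
    )
    ref_summary <- reference_run$summary[
      reference_run$summary$scenario_id == ref$scenario_id &
        reference_run$summary$response == ref$response, ]
    rows[[key]] <- dplyr::bind_cols(
      tibble::tibble(scenario_id = ref$scenario_id, response = ref$response),
      report,
      tibble::tibble(
        included = isTRUE(ref_summary$val_p < 0.05) &&
          isTRUE(ref_summary$null_support <= null_cutoff)
      )
    )
    grids[[key]] <- transferred
  }
  structure(
    list(summary = dplyr::bind_rows(rows), grids = grids, use = use,
         hash = rlang::hash(list(reference_run$hash, target_run$hash, use,
                                 tolerance))),
    class = "transfer_run"
  )
}

#' @export
print.transfer_run <- function(x, ...) {
  cat("<transfer_run> ", nrow(x$summary), " transfer(s), ", x$use,
      " predictions\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write run artifacts as CSV with provenance
#'
#' Writes the summary table of a reference or transfer run to CSV; a JSON
#' sidecar records the run's configuration hash and seed so outputs can be
#' traced to the exact run that produced them.
#'
#' @param run A `reference_run` or `transfer_run`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files.
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir, name = class(run)[1]) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  meta <- file.path(dir, paste0(name, "_meta.json"))
  utils::write.csv(run$summary, csv, row.names = FALSE)
  jsonlite::write_json(
    list(hash = run$hash, seed = run$seed %||% NA,
         version = as.character(utils::packageVersion("reeftransfer"))),
    meta, auto_unbox = TRUE
  )
  invisible(c(csv = csv, meta = meta))
}
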