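# Model transfer: clipped grid predictions in a target system and the
# four-part transferability metric suite.

#' Predict an abundance model onto a grid with calibration clipping
#'
#' Applies a fitted model (or a model-averaged candidate set) to a predictor
#' grid expressed in the *reference* system's centred coordinates, and clips
#' every cell where any predictor used by the model falls outside the
#' reference calibration range — no extrapolation beyond the environmental
#' space seen during fitting. Clipped cells carry no prediction.
#'
#' @param fit An `nb_fit`, or a `ranked_models` table for model-averaged
#'   predictions.
#' @param grid_pset A `predictor_set` built from the target grid with the
#'   reference system's centering constants
#'   (`build_predictor_set(..., centers = predictor_centers(ref))`).
#' @param calibration The reference `predictor_set` (or its `ranges` tibble)
#'   defining per-predictor calibration ranges.
#' @return A `prediction_grid` tibble: `node_id`, `longitude`, `latitude`,
#'   `fit`, `se`, `clipped`. Predictions are `NA` on clipped cells. An
#'   all-clipped grid is returned, not an error.
#' @export
predict_grid_clipped <- function(fit, grid_pset, calibration) {
  stopifnot(inherits(grid_pset, "predictor_set"))
  ranges <- if (inherits(calibration, "predictor_set")) {
    calibration$ranges
  } else {
    calibration
  }
  terms <- if (inherits(fit, "ranked_models")) {
    unique(unlist(lapply(attr(fit, "fits"), function(f) f$terms)))
  } else {
    fit$terms
  }
  used <- unique(base_name(terms))
  data <- grid_pset$data
  clipped <- rep(FALSE, nrow(data))
  for (p in used) {
    r <- ranges[ranges$predictor == p, ]
    if (nrow(r) == 0) abort(paste0("no calibration range for predictor '",
                                   p, "'"))
    clipped <- clipped | data[[p]] < r$min | data[[p]] > r$max
  }
  out <- tibble::tibble(
    node_id = data$node_id,
    longitude = data$longitude, latitude = data$latitude,
    fit = NA_real_, se = NA_real_, clipped = clipped
  )
  if (any(!clipped)) {
    sub <- data[!clipped, , drop = FALSE]
    pred <- if (inherits(fit, "ranked_models")) {
      model_average_predictions(fit, sub)
    } else {
      predict_response(fit, sub, mode = "population")
    }
    out$fit[!clipped] <- pred$fit
    out$se[!clipped] <- pred$se
  }
  class(out) <- c("prediction_grid", class(out))
  out
}

joint_cells <- function(transferred, reference) {
  j <- dplyr::inner_join(
    dplyr::filter(tibble::as_tibble(transferred), !.data$clipped),
    dplyr::filter(tibble::as_tibble(reference), !.data$clipped),
    by = "node_id", suffix = c("_t", "_r")
  )
  if (nrow(j) == 0) abort("no jointly unclipped grid cells to compare")
  j
}

#' Mean absolute grid-cell difference between two prediction grids
#'
#' Per jointly-unclipped cell, `|transferred - reference|`; aggregated as
#' mean and SD, plus the percentage form `100 |t - r| / r` (mean and SD).
#'
#' @param transferred,reference `prediction_grid` tibbles on the same node
#'   set.
#' @return One-row tibble: `abs_diff_mean`, `abs_diff_sd`, `pct_diff_mean`,
#'   `pct_diff_sd`, `n_cells`.
#' @export
grid_abs_difference <- function(transferred, reference) {
  j <- joint_cells(transferred, reference)
  d <- abs(j$fit_t - j$fit_r)
  pct <- 100 * d / j$fit_r
  tibble::tibble(
    abs_diff_mean = mean(d), abs_diff_sd = sd(d),
    pct_diff_mean = mean(pct), pct_diff_sd = sd(pct),
    n_cells = nrow(j)
  )
}

#' Percentage of grid cells within a relative tolerance of the reference
#'
#' Fraction (as a percent) of jointly-unclipped cells where the transferred
#' prediction differs from the reference prediction by at most
#' `tolerance * reference` (boundary inclusive). Cells with a zero reference
#' prediction are excluded and counted.
#'
#' @inheritParams grid_abs_difference
#' @param tolerance Relative tolerance (default 0.15, i.e. <= 15%).
#' @return One-row tibble: `pct_within`, `n_cells`, `n_excluded`.
#' @export
pct_within_tolerance <- function(transferred, reference, tolerance = 0.15) {
  j <- joint_cells(transferred, reference)
  zero <- j$fit_r == 0
  j <- j[!zero, , drop = FALSE]
  if (nrow(j) == 0) abort("all reference cells are zero")
  within <- abs(j$fit_t - j$fit_r) / j$fit_r <= tolerance
  tibble::tibble(pct_within = 100 * mean(within), n_cells = nrow(j),
                 n_excluded = sum(zero))
}

#' Affine min-max rescaling
#'
#' Maps the input's `(min, max)` onto `(target_min, target_max)`; used to put
#' a transferred prediction surface on the same scale as the reference before
#' comparing spatial pattern.
#'
#' @param values Numeric vector with `max > min`.
#' @param target_min,target_max Target range.
#' @return Rescaled numeric vector.
#' @export
rescale_minmax <- function(values, target_min, target_max) {
  lo <- min(values); hi <- max(values)
  if (hi <= lo) abort("constant input: min-max rescale undefined")
  target_min + (values - lo) / (hi - lo) * (target_max - target_min)
}

#' High-versus-low spatial pattern agreement
#'
#' The transferred predictions are rescaled to the reference's min and max,
#' each grid's cells are classified high or low relative to that grid's own
#' threshold (median by default; ties count as low), and the percentage of
#' jointly-unclipped cells with matching classes is returned.
#'
#' @inheritParams grid_abs_difference
#' @param threshold `"median"` (default) or `"midrange"` (mean of min and
#'   max).
#' @return One-row tibble: `pct_agreement`, `n_cells`.
#' @export
high_low_agreement <- function(transferred, reference,
                               threshold = c("median", "midrange")) {
  threshold <- match.arg(threshold)
  j <- joint_cells(transferred, reference)
  if (sd(j$fit_t) == 0 || sd(j$fit_r) == 0) {
    abort("constant prediction grid: high/low classes undefined")
  }
  t_resc <- rescale_minmax(j$fit_t, min(j$fit_r), max(j$fit_r))
  cut_of <- function(x) switch(threshold,
    median = median(x),
    midrange = (min(x) + max(x)) / 2
  )
  cls_t <- t_resc > cut_of(t_resc)
  cls_r <- j$fit_r > cut_of(j$fit_r)
  tibble::tibble(pct_agreement = 100 * mean(cls_t == cls_r),
                 n_cells = nrow(j))
}

#' Assemble the four-part transferability report
#'
#' Compares a transferred prediction grid against the target system's own
#' reference grid with the four metrics: (i) direct validation of the
#' transferred predictions against observed counts at the target's surveyed
#' sites, (ii) mean absolute grid-cell difference (and percentage form),
#' (iii) percentage of cells within a relative tolerance of the reference,
#' and (iv) high-versus-low pattern agreement after min-max rescaling.
#' Degenerate metrics (constant grids, no joint cells) are reported as `NA`
#' with a note instead of failing.
#'
#' @inheritParams grid_abs_difference
#' @param observed Observed counts at the target system's surveyed sites
#'   (optional; metric i is `NA` without them).
#' @param predicted_at_sites Transferred-model predictions at those sites.
#' @param tolerance Relative tolerance for metric iii (default 0.15).
#' @return A one-row `transfer_report` tibble carrying all four metrics,
#'   prediction ranges, cell counts and a `note` column.
#' @export
transfer_report <- function(transferred, reference, observed = NULL,
                            predicted_at_sites = NULL, tolerance = 0.15) {
  notes <- character(0)
  val <- tibble::tibble(r2_pct = NA_real_, p_value = NA_real_)
  if (!is.null(observed) && !is.null(predicted_at_sites)) {
    v <- direct_validation(observed, predicted_at_sites)
    val <- v[, c("r2_pct", "p_value")]
    if (!is.na(v$note)) notes <- c(notes, v$note)
  }
  metric <- function(expr) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, conditionMessage(e))
      NULL
    })
  }
  d <- metric(grid_abs_difference(transferred, reference))
  w <- metric(pct_within_tolerance(transferred, reference, tolerance))
  h <- metric(high_low_agreement(transferred, reference))
  unclipped_t <- tibble::as_tibble(transferred) |>
    dplyr::filter(!.data$clipped)
  out <- tibble::tibble(
    val_r2_pct = val$r2_pct, val_p = val$p_value,
    pred_min = if (nrow(unclipped_t) > 0) min(unclipped_t$fit) else NA_real_,
    pred_max = if (nrow(unclipped_t) > 0) max(unclipped_t$fit) else NA_real_,
    abs_diff_mean = d$abs_diff_mean %||% NA_real_,
    abs_diff_sd = d$abs_diff_sd %||% NA_real_,
    pct_diff_mean = d$pct_diff_mean %||% NA_real_,
    pct_diff_sd = d$pct_diff_sd %||% NA_real_,
    pct_within = w$pct_within %||% NA_real_,
    pct_high_low = h$pct_agreement %||% NA_real_,
    n_cells = d$n_cells %||% 0L,
    n_clipped_transferred = sum(transferred$clipped),
    n_clipped_reference = sum(reference$clipped),
    tolerance = tolerance,
    note = if (length(notes) == 0) NA_character_ else
      paste(notes, collapse = "; ")
  )
  class(out) <- c("transfer_report", class(out))
  out
}

#' Plot a prediction grid
#'
#' Tile map of predicted abundance; clipped cells are drawn in grey.
#'
#' @param object A `prediction_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prediction_grid
#' @export
autoplot.prediction_grid <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fit)) +
    ggplot2::geom_tile(data = df[df$clipped, , drop = FALSE],
                       fill = "grey80") +
    ggplot2::scale_fill_viridis_c(name = "Predicted N", na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}
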