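# Multimodel inference: AICc weights, variance explained, effect sizes and
# model-averaged predictions over the fixed candidate set.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`, with `k` the total parameter
#' count (fixed effects + dispersion + variance component when present).
#'
#' @param fit An `nb_fit`, or a log-likelihood value when `k` and `n` are
#'   given explicitly.
#' @param k,n Parameter count and sample size (only when `fit` is numeric).
#' @return A single number.
#' @export
#' @examples
#' aicc(-50, k = 3, n = 100)  # 106.25
aicc <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "nb_fit")) {
    ll <- fit$loglik; k <- fit$k; n <- fit$n
  } else {
    stopifnot(is.numeric(fit), !is.null(k), !is.null(n))
    ll <- fit
  }
  if (n <= k + 1) abort("AICc undefined: n must exceed k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`. Invariant to adding a constant to all
#' AICc values; weights sum to 1.
#'
#' @param aicc_values Numeric vector.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
akaike_weights <- function(aicc_values) {
  rel <- exp(-(aicc_values - min(aicc_values)) / 2)
  rel / sum(rel)
}

#' Rank a candidate set of fitted abundance models by AICc weight
#'
#' All fits must be to the identical response vector. Per model the table
#' carries AICc, delta-AICc, the Akaike weight, and variance explained:
#' marginal/conditional R-squared for mixed fits, percent deviance explained
#' for plain GLMs. Ranking is by weight, ties broken by smaller `k` then lower
#' `model_id`. Top models are all models inside the smallest set whose
#' cumulative weight reaches `top_cum_weight`.
#'
#' @param fits List of `nb_fit` objects (one per candidate model).
#' @param top_cum_weight Cumulative-weight cutoff for the top-model set
#'   (default 0.9).
#' @return A `ranked_models` tibble with one row per model, carrying the fits
#'   and summary attributes; see also [top_models()] and [null_support()].
#' @export
waicc_rank <- function(fits, top_cum_weight = 0.9) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "nb_fit")))
  y0 <- fits[[1]]$data[[fits[[1]]$response]]
  same <- vapply(fits, function(f) {
    identical(f$data[[f$response]], y0)
  }, logical(1))
  if (!all(same)) abort("all fits must share an identical response vector")

  rows <- purrr::map_dfr(fits, function(f) {
    is_glmm <- !is.null(f$group)
    r2 <- if (is_glmm) r2_nakagawa(f) else
      list(r2m = NA_real_, r2c = NA_real_)
    tibble::tibble(
      model_id = f$model_id %||% NA_integer_,
      k = f$k, loglik = f$loglik, aicc = aicc(f),
      r2m = r2$r2m, r2c = r2$r2c,
      de_pct = if (is_glmm) NA_real_ else deviance_explained(f)
    )
  })
  rows$delta_aicc <- rows$aicc - min(rows$aicc)
  rows$waicc <- akaike_weights(rows$aicc)
  ord <- order(-rows$waicc, rows$k, rows$model_id)
  rows <- rows[ord, ]
  rows$rank <- seq_len(nrow(rows))
  top_n <- which(cumsum(rows$waicc) >= top_cum_weight - 1e-12)[1]
  out <- tibble::new_tibble(
    rows,
    fits = fits[ord],
    top_models = rows$model_id[seq_len(top_n)],
    null_support = if (any(rows$model_id == 12, na.rm = TRUE)) {
      rows$waicc[which(rows$model_id == 12)]
    } else NA_real_,
    class = "ranked_models"
  )
  out
}

#' @export
print.ranked_models <- function(x, ...) {
  cat("<ranked_models> ", nrow(x), " models; top set: ",
      paste(attr(x, "top_models"), collapse = ", "),
      "; null-model weight: ",
      format(attr(x, "null_support"), digits = 3), "\n", sep = "")
  NextMethod()
}

#' @rdname waicc_rank
#' @param x A `ranked_models` table.
#' @param ... Unused.
#' @method tidy ranked_models
#' @export
tidy.ranked_models <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Models forming the cumulative top-weight set
#'
#' @param ranked A `ranked_models` table.
#' @return Integer vector of model ids.
#' @export
top_models <- function(ranked) attr(ranked, "top_models")

#' Akaike weight of the null (intercept-only) model
#'
#' @param ranked A `ranked_models` table.
#' @return A single number (`NA` if model 12 was not in the set).
#' @export
null_support <- function(ranked) attr(ranked, "null_support")

#' Marginal and conditional R-squared for a mixed count model
#'
#' Variance-component decomposition on the latent (log-link) scale:
#' `R2m = var_f / (var_f + var_alpha + var_d)` and
#' `R2c = (var_f + var_alpha) / (var_f + var_alpha + var_d)`, where `var_f`
#' is the variance of the fixed-effect linear predictor over the fitting
#' sites, `var_alpha` the random-intercept variance, and `var_d` the
#' distribution-specific variance of the NB2 family with log link. The
#' default distribution variance is the lognormal approximation
#' `log(1 + 1/lambda + 1/theta)` with `lambda` the mean observed count; a
#' delta-method (trigamma) variant is available.
#'
#' @param fit An `nb_fit` with a random intercept.
#' @param dist_variance `"lognormal"` (default) or `"trigamma"`.
#' @return List with `r2m`, `r2c`, and the three variance components.
#' @export
r2_nakagawa <- function(fit, dist_variance = c("lognormal", "trigamma")) {
  dist_variance <- match.arg(dist_variance)
  stopifnot(inherits(fit, "nb_fit"))
  if (is.null(fit$group)) {
    abort("r2_nakagawa() needs a random-intercept fit; use deviance_explained()")
  }
  X <- nb_design_matrix(fit, fit$data)
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  var_f <- var(drop(X %*% beta[colnames(X)]))
  var_alpha <- fit$sigma_alpha2
  lambda <- mean(fit$data[[fit$response]])
  var_d <- switch(dist_variance,
    lognormal = log(1 + 1 / lambda + 1 / fit$theta),
    trigamma = trigamma(1 / (1 / lambda + 1 / fit$theta))
  )
  total <- var_f + var_alpha + var_d
  if (total == 0) abort("zero total latent variance; R-squared undefined")
  list(r2m = var_f / total, r2c = (var_f + var_alpha) / total,
       var_fixed = var_f, var_random = var_alpha, var_dist = var_d)
}

#' Percent deviance explained by a GLM
#'
#' `100 * (1 - residual deviance / null deviance)`.
#'
#' @param fit An `nb_fit` without random effects.
#' @return A percentage.
#' @export
deviance_explained <- function(fit) {
  stopifnot(inherits(fit, "nb_fit"))
  if (!is.null(fit$group)) {
    abort("deviance_explained() is defined for GLM fits; use r2_nakagawa()")
  }
  if (is.na(fit$null_deviance) || fit$null_deviance == 0) {
    abort("null deviance is zero; deviance explained undefined")
  }
  100 * (1 - fit$deviance / fit$null_deviance)
}

#' Weight-averaged standardized effect sizes per predictor
#'
#' For each predictor (design column), the Akaike-weight-averaged magnitude of
#' its standardized coefficient — `|coefficient| * sd(column)` over the
#' fitting sites — across the models that contain it, with weights
#' renormalized over those models (absence is exclusion, not a zero
#' coefficient). Quadratic columns are standardized by the SD of the squared
#' centred column. The predictor maximizing the average is reported as the
#' highest-effect predictor.
#'
#' @param ranked A `ranked_models` table from [waicc_rank()].
#' @return Tibble with `predictor`, `effect`, `n_models`, `total_weight`,
#'   sorted by decreasing effect; the first row is the highest-effect
#'   predictor.
#' @export
effect_sizes <- function(ranked) {
  fits <- attr(ranked, "fits")
  w <- ranked$waicc
  preds <- unique(unlist(lapply(fits, function(f) f$terms)))
  if (length(preds) == 0) {
    return(tibble::tibble(predictor = character(0), effect = numeric(0),
                          n_models = integer(0), total_weight = numeric(0)))
  }
  rows <- purrr::map_dfr(preds, function(p) {
    has <- vapply(fits, function(f) p %in% f$terms, logical(1))
    es <- vapply(fits[has], function(f) {
      b <- f$coefficients$estimate[f$coefficients$term == p]
      abs(b) * sd(f$data[[p]])
    }, numeric(1))
    wi <- w[has]
    tibble::tibble(predictor = p,
                   effect = sum(wi * es) / sum(wi),
                   n_models = sum(has), total_weight = sum(wi))
  })
  dplyr::arrange(rows, dplyr::desc(.data$effect))
}

#' Model-averaged predictions over the candidate set
#'
#' Akaike-weight-weighted mean of the per-model response-scale predictions
#' (population mode); the accompanying `se` is the weighted mean of the
#' per-model delta-method standard errors.
#'
#' @param ranked A `ranked_models` table.
#' @param newdata Design tibble resolvable by every fit in the set.
#' @param mode Passed to [predict_response()].
#' @return Tibble with `fit` and `se`.
#' @export
model_average_predictions <- function(ranked, newdata, mode = "population") {
  fits <- attr(ranked, "fits")
  w <- ranked$waicc
  preds <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    preds[[i]] <- tryCatch(
      predict_response(fits[[i]], newdata, mode = mode),
      error = function(e) {
        abort(paste0("model ", fits[[i]]$model_id %||% i,
                     " unresolvable on newdata: ", conditionMessage(e)))
      }
    )
  }
  fit_mat <- vapply(preds, function(p) p$fit, numeric(nrow(newdata)))
  se_mat <- vapply(preds, function(p) p$se, numeric(nrow(newdata)))
  if (nrow(newdata) == 1) {
    fit_mat <- matrix(fit_mat, nrow = 1)
    se_mat <- matrix(se_mat, nrow = 1)
  }
  tibble::tibble(fit = drop(fit_mat %*% w), se = drop(se_mat %*% w))
}
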