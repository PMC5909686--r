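# Validation: grouped k-fold cross-validation, direct observed-vs-predicted
# validation, and Moran's I correlogram diagnostics.

#' Reef-stratified k-fold cross-validation of an abundance model
#'
#' Sites are dealt into `k` folds round-robin within each reef (after a
#' seeded shuffle), so every training set retains every reef wherever reef
#' sizes allow — keeping the random-intercept design estimable. Per fold the
#' model is refitted on the training sites and held-out sites are predicted
#' in population mode; the fold error is the mean absolute difference between
#' observed and predicted counts, and the percentage error is the fold error
#' relative to the fold's mean observed count.
#'
#' @param data Model data tibble (response + design columns + grouping
#'   column).
#' @param terms Design column names of the model to cross-validate.
#' @param group Grouping column for the random intercept, or `NULL` for a
#'   GLM.
#' @param response Count column name.
#' @param k Number of folds (default 10); `k = nrow(data)` gives
#'   leave-one-out.
#' @param seed Integer seed for the fold assignment.
#' @return A `cv_result`: list with `per_fold` (tibble of fold errors),
#'   `error_mean`, `error_sd`, `pct_mean`, `pct_sd`, `folds` (assignment
#'   vector), `events` (notes, e.g. reefs absent from a training set), `k`,
#'   `seed`.
#' @export
kfold_cv <- function(data, terms = character(0), group = "reef_id",
                     response = "pooled_count", k = 10, seed = 1L) {
  n <- nrow(data)
  stopifnot(k >= 2, k <= n)
  strata <- if (!is.null(group)) data[[group]] else rep(1, n)
  folds <- withr::with_seed(seed, {
    f <- integer(n)
    offset <- 0L
    for (g in unique(strata)) {
      idx <- sample(which(strata == g))
      f[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
    f
  })
  events <- character(0)
  per_fold <- purrr::map_dfr(seq_len(k), function(j) {
    train <- data[folds != j, , drop = FALSE]
    test <- data[folds == j, , drop = FALSE]
    if (nrow(test) == 0) return(NULL)
    if (!is.null(group)) {
      lost <- setdiff(unique(test[[group]]), unique(train[[group]]))
      if (length(lost) > 0) {
        events <<- c(events, paste0("fold ", j,
                                    ": population fallback for reef(s) ",
                                    paste(lost, collapse = ", ")))
      }
      refit <- fit_nb_glmm(train, terms, group = group, response = response)
    } else {
      refit <- fit_nb_glm(train, terms, response = response)
    }
    pred <- predict_response(refit, test, mode = "population")$fit
    obs <- test[[response]]
    mae <- mean(abs(obs - pred))
    tibble::tibble(fold = j, n_test = nrow(test), error = mae,
                   pct_error = 100 * mae / mean(obs))
  })
  structure(
    list(per_fold = per_fold,
         error_mean = mean(per_fold$error), error_sd = sd(per_fold$error),
         pct_mean = mean(per_fold$pct_error), pct_sd = sd(per_fold$pct_error),
         folds = folds, events = events, k = k, seed = seed),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$k, "-fold: error ",
      format(x$error_mean, digits = 4), " +/- ",
      format(x$error_sd, digits = 4), " (",
      format(x$pct_mean, digits = 4), " +/- ",
      format(x$pct_sd, digits = 4), "%)\n", sep = "")
  if (length(x$events) > 0) cat("  ", length(x$events), " fold event(s)\n")
  invisible(x)
}

#' @rdname kfold_cv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(k = x$k, error_mean = x$error_mean, error_sd = x$error_sd,
                 pct_mean = x$pct_mean, pct_sd = x$pct_sd,
                 n_events = length(x$events))
}

#' Direct validation of predictions against observations
#'
#' Ordinary least-squares regression of observed counts on predicted counts;
#' reports the coefficient of determination as a percentage and the two-sided
#' p-value of the slope (equivalent to the regression F-test with one
#' predictor). Constant predictions leave the validation undefined; this is
#' reported as an `NA` row with a note rather than an error so that summary
#' tables can carry it.
#'
#' @param observed,predicted Numeric vectors of equal length (`>= 3`).
#' @return One-row tibble: `r2_pct`, `p_value`, `n`, `note`.
#' @export
direct_validation <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (sd(predicted) == 0) {
    return(tibble::tibble(r2_pct = NA_real_, p_value = NA_real_,
                          n = length(observed),
                          note = "constant predictions: validation undefined"))
  }
  m <- lm(observed ~ predicted)
  s <- summary(m)
  tibble::tibble(r2_pct = 100 * s$r.squared,
                 p_value = s$coefficients["predicted", 4],
                 n = length(observed), note = NA_character_)
}

# Moran's I for a symmetric weight matrix, with first and second moments
# under the normality assumption (Cliff & Ord); weights are used as given
# (binary band membership), not row-standardized.
moran_i_binary <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(W)
  obs <- (n / s0) * sum(W * outer(z, z)) / sum(z^2)
  e_i <- -1 / (n - 1)
  s1 <- 0.5 * sum((W + t(W))^2)
  s2 <- sum((rowSums(W) + colSums(W))^2)
  var_i <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - e_i^2
  sd_i <- sqrt(var_i)
  list(observed = obs, expected = e_i, sd = sd_i,
       p_value = 2 * pnorm(-abs((obs - e_i) / sd_i)))
}

#' Moran's I correlogram of model residuals
#'
#' Spatial autocorrelation of residuals across distance bands. For band `b`,
#' binary weights `w_ij = 1` when the planar distance between sites i and j
#' falls in the band, and Moran's I is the weighted cross-product statistic
#' `(n/W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' residuals and `W` the total weight. Each band also carries the null
#' expectation `-1/(n-1)`, the standard deviation under the normality
#' assumption, and a two-sided p-value. Bands are equal-width; the default
#' width is the first decile of the pairwise distance distribution.
#'
#' @param residuals Numeric vector of residuals (deviance residuals of the
#'   fitted model by convention; any residual type may be supplied).
#' @param coords Tibble/data frame with `longitude`, `latitude` for the same
#'   rows.
#' @param band_width_km Width of each distance band (km); default: first
#'   decile of pairwise distances.
#' @param n_bands Number of bands (default 10).
#' @return A `moran_correlogram` tibble: `lag`, `d_min`, `d_max`, `n_pairs`,
#'   `moran_i`, `expected`, `sd`, `p_value`. Empty bands are dropped with a
#'   note in the `bands_skipped` attribute.
#' @export
moran_correlogram <- function(residuals, coords, band_width_km = NULL,
                              n_bands = 10) {
  n <- length(residuals)
  stopifnot(n == nrow(coords), n >= 4)
  if (sd(residuals) == 0) abort("zero residual variance; Moran's I undefined")
  D <- pairwise_dist_km(coords$longitude, coords$latitude)
  off <- D[upper.tri(D)]
  band_width_km <- band_width_km %||% as.numeric(quantile(off, 0.1))
  if (band_width_km <= 0) abort("degenerate coordinates: zero band width")
  skipped <- integer(0)
  rows <- purrr::map_dfr(seq_len(n_bands), function(b) {
    lo <- (b - 1) * band_width_km
    hi <- b * band_width_km
    W <- D > lo & D <= hi
    mode(W) <- "numeric"
    diag(W) <- 0
    if (sum(W) == 0) {
      skipped <<- c(skipped, b)
      return(NULL)
    }
    m <- moran_i_binary(residuals, W)
    tibble::tibble(lag = b, d_min = lo, d_max = hi, n_pairs = sum(W) / 2,
                   moran_i = m$observed, expected = m$expected, sd = m$sd,
                   p_value = m$p_value)
  })
  out <- tibble::new_tibble(rows, band_width_km = band_width_km,
                            bands_skipped = skipped,
                            class = "moran_correlogram")
  out
}

#' First-lag Moran's I of a correlogram
#'
#' @param correlogram A `moran_correlogram`.
#' @return A single number.
#' @export
first_lag_moran <- function(correlogram) {
  correlogram$moran_i[which.min(correlogram$lag)]
}

#' Plot a Moran's I correlogram
#'
#' Observed Moran's I per distance band with the null expectation `-1/(n-1)`
#' as a dashed reference line; filled points mark bands with `p < 0.05`.
#'
#' @param object A `moran_correlogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moran_correlogram
#' @export
autoplot.moran_correlogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$p_value < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$d_min + .data$d_max) / 2,
                                   y = .data$moran_i)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$expected),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white"),
                               name = "p < 0.05") +
    ggplot2::labs(x = "Distance band midpoint (km)", y = "Moran's I") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation errors per fold
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$pct_error)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$pct_mean, linetype = "dashed") +
    ggplot2::labs(x = "Fold", y = "Percentage prediction error") +
    ggplot2::theme_minimal()
}
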