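# Negative-binomial count models with log link, with and without a reef-level
# random intercept, behind a uniform fit-object surface.
#
# Estimation is delegated to the standard implementations: MASS::glm.nb for
# the GLM and glmmTMB (nbinom2 family, ML, Laplace approximation for the
# scalar random intercept) for the GLMM. Both use the NB2 parameterization,
# variance = mu + mu^2 / theta. The wrapper records everything multimodel
# inference and transfer need: coefficients with SEs, theta, the
# random-intercept variance, the log-likelihood and its parameter count
# (fixed effects + theta + variance component when present), fitted values,
# deviances, and conditional modes.

nb_formula <- function(terms, response = "count", group = NULL) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  if (!is.null(group)) rhs <- paste0(rhs, " + (1 | ", group, ")")
  as.formula(paste(response, "~", rhs))
}

check_fit_inputs <- function(data, terms, response) {
  missing_cols <- setdiff(c(response, terms), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s) in model data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  y <- data[[response]]
  if (any(y < 0) || any(y != floor(y))) {
    abort("response must contain non-negative integer counts")
  }
  if (length(terms) > 0) {
    X <- model.matrix(nb_formula(terms, response), data)
    if (qr(X)$rank < ncol(X)) {
      abort("rank-deficient design; check for collinear predictor columns")
    }
  }
  invisible(y)
}

new_nb_fit <- function(engine, data, terms, response, group, model_id) {
  is_glmm <- !is.null(group)
  ll <- logLik(engine)
  if (is_glmm) {
    fe <- glmmTMB::fixef(engine)$cond
    se <- sqrt(diag(vcov(engine)$cond))
    theta <- glmmTMB::sigma(engine)
    vc <- glmmTMB::VarCorr(engine)$cond[[group]]
    sigma_alpha2 <- as.numeric(vc[1, 1])
    modes <- glmmTMB::ranef(engine)$cond[[group]]
    cond_modes <- setNames(modes[[1]], rownames(modes))
    deviance <- NA_real_
    null_deviance <- NA_real_
    converged <- engine$fit$convergence == 0 && engine$sdr$pdHess
  } else {
    fe <- coef(engine)
    se <- sqrt(diag(vcov(engine)))
    theta <- engine$theta
    sigma_alpha2 <- NA_real_
    cond_modes <- NULL
    deviance <- engine$deviance
    null_deviance <- engine$null.deviance
    converged <- engine$converged
  }
  if (!converged) {
    abort(paste0("negative-binomial fit did not converge (model ",
                 model_id %||% "?", ", terms: ",
                 paste(terms, collapse = " + "), ")"))
  }
  # uniform parameter count: fixed effects + theta (+ variance component)
  k <- length(fe) + 1L + as.integer(is_glmm)
  structure(
    list(
      engine = engine,
      coefficients = tibble::tibble(term = names(fe), estimate = unname(fe),
                                    std_error = unname(se)),
      theta = theta, sigma_alpha2 = sigma_alpha2,
      conditional_modes = cond_modes,
      loglik = as.numeric(ll), k = k, n = nrow(data),
      deviance = deviance, null_deviance = null_deviance,
      fitted = unname(fitted(engine)),
      terms = terms, response = response, group = group,
      model_id = model_id, data = data
    ),
    class = "nb_fit"
  )
}

#' Fit a negative-binomial GLM (log link)
#'
#' Joint maximum likelihood for the regression coefficients and the NB2
#' dispersion `theta` via [MASS::glm.nb()] with a tightened convergence
#' tolerance. The parameter count `k` includes `theta`.
#'
#' @param data Tibble holding the response and the (already centred) design
#'   columns.
#' @param terms Character vector of design column names; `character(0)` fits
#'   the intercept-only null model.
#' @param response Name of the count column (default `"pooled_count"`).
#' @param model_id Optional candidate-set id carried through to rankings.
#' @return An `nb_fit` object.
#' @export
fit_nb_glm <- function(data, terms = character(0),
                       response = "pooled_count", model_id = NULL) {
  check_fit_inputs(data, terms, response)
  engine <- tryCatch(
    suppressWarnings(MASS::glm.nb(
      nb_formula(terms, response), data = data,
      control = stats::glm.control(epsilon = 1e-12, maxit = 200)
    )),
    error = function(e) NULL
  )
  if (is.null(engine) || !engine$converged) {
    # theta MLE diverges on under/equidispersed samples; the NB then
    # degenerates to its Poisson limit, fitted with theta pinned large
    theta_cap <- 1e7
    engine <- suppressWarnings(stats::glm(
      nb_formula(terms, response), data = data,
      family = MASS::negative.binomial(theta = theta_cap)
    ))
    engine$theta <- theta_cap
  }
  new_nb_fit(engine, data, terms, response, group = NULL, model_id = model_id)
}

#' Fit a negative-binomial GLMM with a reef-level random intercept
#'
#' Maximum likelihood with the scalar random intercept integrated out by the
#' Laplace approximation (via [glmmTMB::glmmTMB()], `nbinom2` family). A
#' random-intercept variance estimated at the zero boundary is a valid fit,
#' not a failure. `k` counts the fixed effects, `theta`, and the variance
#' component.
#'
#' @inheritParams fit_nb_glm
#' @param group Name of the grouping column (default `"reef_id"`); must have
#'   `>= 2` levels.
#' @return An `nb_fit` object with `sigma_alpha2` and conditional modes.
#' @export
fit_nb_glmm <- function(data, terms = character(0), group = "reef_id",
                        response = "pooled_count", model_id = NULL) {
  check_fit_inputs(data, terms, response)
  if (!group %in% names(data)) {
    abort(paste0("grouping column '", group, "' not found"))
  }
  if (length(unique(data[[group]])) < 2) {
    abort("random intercept needs at least 2 groups")
  }
  data[[group]] <- factor(data[[group]])
  form <- nb_formula(terms, response, group)
  engine <- suppressWarnings(glmmTMB::glmmTMB(
    form, data = data, family = glmmTMB::nbinom2()
  ))
  ok <- engine$fit$convergence == 0 && isTRUE(engine$sdr$pdHess)
  if (!ok) {
    # one retry with a BFGS outer optimizer before declaring failure
    engine <- suppressWarnings(glmmTMB::glmmTMB(
      form, data = data, family = glmmTMB::nbinom2(),
      control = glmmTMB::glmmTMBControl(
        optimizer = stats::optim, optArgs = list(method = "BFGS")
      )
    ))
  }
  new_nb_fit(engine, data, terms, response, group = group,
             model_id = model_id)
}

#' @export
print.nb_fit <- function(x, ...) {
  kind <- if (is.null(x$group)) "NB GLM" else
    paste0("NB GLMM (random intercept: ", x$group, ")")
  cat("<nb_fit> ", kind, if (!is.null(x$model_id))
    paste0(", model ", x$model_id), "\n", sep = "")
  cat("  n = ", x$n, ", k = ", x$k, ", logLik = ",
      format(x$loglik, digits = 6), ", theta = ",
      format(x$theta, digits = 4), sep = "")
  if (!is.na(x$sigma_alpha2)) {
    cat(", sigma_alpha^2 = ", format(x$sigma_alpha2, digits = 4), sep = "")
  }
  cat("\n  terms: ", if (length(x$terms) == 0) "(intercept only)" else
    paste(x$terms, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_nb_glm
#' @param x An `nb_fit`.
#' @param ... Unused.
#' @method tidy nb_fit
#' @export
tidy.nb_fit <- function(x, ...) {
  x$coefficients |>
    dplyr::mutate(
      statistic = .data$estimate / .data$std_error,
      p_value = 2 * pnorm(-abs(.data$statistic))
    )
}

#' @rdname fit_nb_glm
#' @method glance nb_fit
#' @export
glance.nb_fit <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id %||% NA_integer_,
    n = x$n, k = x$k, loglik = x$loglik, aicc = aicc(x),
    theta = x$theta, sigma_alpha2 = x$sigma_alpha2,
    deviance = x$deviance, null_deviance = x$null_deviance
  )
}

# Fixed-effect linear predictor (and its covariance pieces) on new data.
nb_design_matrix <- function(fit, newdata) {
  missing_cols <- setdiff(fit$terms, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata lacks design column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rhs <- if (length(fit$terms) == 0) "1" else
    paste(fit$terms, collapse = " + ")
  model.matrix(as.formula(paste("~", rhs)), newdata)
}

nb_vcov <- function(fit) {
  if (is.null(fit$group)) vcov(fit$engine) else vcov(fit$engine)$cond
}

#' Predict expected counts from a fitted abundance model
#'
#' Population mode returns `exp(X beta)` with a delta-method standard error on
#' the response scale. Conditional mode adds the reef's conditional mode to
#' the linear predictor when the reef was seen during fitting, and falls back
#' to the population prediction for unseen reefs (a new reef has no mode).
#'
#' @param fit An `nb_fit`.
#' @param newdata Tibble carrying the fit's design columns, centred with the
#'   fit's centering constants (and the grouping column for conditional mode).
#' @param mode `"population"` or `"conditional"`.
#' @return Tibble with `fit` (expected count) and `se` (response scale).
#' @export
predict_response <- function(fit, newdata,
                             mode = c("population", "conditional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "nb_fit"))
  X <- nb_design_matrix(fit, newdata)
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  eta <- drop(X %*% beta[colnames(X)])
  V <- nb_vcov(fit)
  se_eta <- sqrt(rowSums((X %*% V[colnames(X), colnames(X)]) * X))
  if (mode == "conditional") {
    if (is.null(fit$group)) {
      abort("conditional prediction requires a random-intercept fit")
    }
    g <- as.character(newdata[[fit$group]])
    add <- fit$conditional_modes[g]
    add[is.na(add)] <- 0  # unseen group: population fallback
    eta <- eta + unname(add)
  }
  mu <- exp(eta)
  tibble::tibble(fit = unname(mu), se = unname(mu * se_eta))
}

#' Fit a Poisson test model (GLMM) for the dispersion check
#'
#' The distributional choice for the count models is justified by fitting a
#' Poisson model first and measuring its overdispersion with
#' [dispersion_statistic()].
#'
#' @inheritParams fit_nb_glmm
#' @param group Grouping column for the random intercept, or `NULL` for a
#'   plain Poisson GLM.
#' @return A fitted model understood by [dispersion_statistic()].
#' @export
fit_poisson_test <- function(data, terms = character(0), group = "reef_id",
                             response = "pooled_count") {
  check_fit_inputs(data, terms, response)
  if (!is.null(group)) {
    data[[group]] <- factor(data[[group]])
    glmmTMB::glmmTMB(nb_formula(terms, response, group), data = data,
                     family = stats::poisson())
  } else {
    stats::glm(nb_formula(terms, response), data = data,
               family = stats::poisson())
  }
}

#' Overdispersion statistic of a fitted Poisson model
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom. Values well above 1 indicate overdispersion relative to the
#' Poisson and motivate the negative-binomial family.
#'
#' @param poisson_fit A fitted Poisson model (`glm` or `glmmTMB`).
#' @return A single number.
#' @export
dispersion_statistic <- function(poisson_fit) {
  pr <- residuals(poisson_fit, type = "pearson")
  df <- length(pr) - attr(logLik(poisson_fit), "df")
  if (df <= 0) abort("no residual degrees of freedom")
  ssq <- sum(pr^2)
  if (ssq == 0) return(0)
  ssq / df
}

#' Residuals of an abundance model fit
#'
#' Deviance residuals (default) use the NB2 deviance with the fit's `theta`;
#' Pearson residuals scale by the NB2 standard deviation
#' `sqrt(mu + mu^2/theta)`. Computed directly from the stored response and
#' fitted values so GLM and GLMM fits behave identically.
#'
#' @param object An `nb_fit`.
#' @param type `"deviance"` or `"pearson"`.
#' @param mode Fitted values to residualize against: `"conditional"` (the
#'   engine's fitted values, including conditional modes for GLMMs) or
#'   `"population"` (fixed effects only).
#' @param ... Unused.
#' @return Numeric vector of residuals.
#' @export
residuals.nb_fit <- function(object, type = c("deviance", "pearson"),
                             mode = c("conditional", "population"), ...) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  y <- object$data[[object$response]]
  mu <- if (mode == "conditional" || is.null(object$group)) {
    object$fitted
  } else {
    predict_response(object, object$data, mode = "population")$fit
  }
  theta <- object$theta
  if (type == "pearson") {
    (y - mu) / sqrt(mu + mu^2 / theta)
  } else {
    term1 <- ifelse(y == 0, 0, y * log(y / mu))
    term2 <- (y + theta) * log((y + theta) / (mu + theta))
    sign(y - mu) * sqrt(pmax(0, 2 * (term1 - term2)))
  }
}
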