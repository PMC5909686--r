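nb_sim <- function(n, beta0, beta1 = NULL, theta = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    eta <- beta0 + if (is.null(beta1)) 0 else beta1 * x
    tibble::tibble(x = x, pooled_count = rnbinom(n, mu = exp(eta),
                                                 size = theta))
  })
}

test_that("intercept-only NB MLE is the log of the sample mean", {
  d <- nb_sim(80, beta0 = log(4), seed = 2)
  fit <- fit_nb_glm(d)
  expect_equal(fit$coefficients$estimate[1], log(mean(d$pooled_count)),
               tolerance = 1e-10)
  expect_equal(fit$k, 2)  # intercept + theta
  expect_true(all(fit$fitted > 0))
})

test_that("near-Poisson data drive theta large without distorting coefficients", {
  d <- withr::with_seed(3, {
    x <- rnorm(400)
    tibble::tibble(x = x, pooled_count = stats::rpois(400, exp(1 + 0.4 * x)))
  })
  fit <- fit_nb_glm(d, "x")
  pois <- stats::glm(pooled_count ~ x, data = d, family = stats::poisson())
  expect_gt(fit$theta, 100)
  se <- summary(pois)$coefficients[, 2]
  expect_true(all(abs(fit$coefficients$estimate - coef(pois)) < 3 * se))
})

test_that("GLM slope recovery is within reported uncertainty at n = 2000", {
  d <- nb_sim(2000, beta0 = 1.0, beta1 = 0.5, theta = 2, seed = 4)
  fit <- fit_nb_glm(d, "x")
  est <- fit$coefficients
  expect_lt(abs(est$estimate[est$term == "x"] - 0.5),
            3 * est$std_error[est$term == "x"])
  expect_lt(abs(fit$theta - 2) / 2, 0.2)
})

test_that("count and rank preconditions are enforced", {
  d <- nb_sim(30, log(5))
  d2 <- dplyr::mutate(d, pooled_count = pooled_count + 0.5)
  expect_error(fit_nb_glm(d2), "integer")
  d3 <- dplyr::mutate(d, x2 = 2 * x)
  expect_error(fit_nb_glm(d3, c("x", "x2")), "collinear|rank")
})

glmm_sim <- function(n_groups = 30, per = 15, sigma_alpha = 0.5, theta = 5,
                     beta = c(1, 0.5), seed = 1) {
  withr::with_seed(seed, {
    g <- rep(sprintf("R%02d", seq_len(n_groups)), each = per)
    x <- rnorm(n_groups * per)
    a <- rnorm(n_groups, 0, sigma_alpha)
    mu <- exp(beta[1] + beta[2] * x + rep(a, each = per))
    tibble::tibble(reef_id = g, x = x,
                   pooled_count = rnbinom(length(mu), mu = mu, size = theta))
  })
}

test_that("a zero-variance random effect degenerates to the GLM", {
  d <- glmm_sim(sigma_alpha = 0, seed = 5)
  glmm <- fit_nb_glmm(d, "x")
  glm <- fit_nb_glm(d, "x")
  expect_lt(glmm$sigma_alpha2, 1e-3)
  expect_equal(glmm$coefficients$estimate, glm$coefficients$estimate,
               tolerance = 1e-3)
  # nesting: the profiled GLMM likelihood cannot fall below the GLM's
  expect_gte(glmm$loglik, glm$loglik - 1e-6)
  expect_equal(glmm$loglik, glm$loglik, tolerance = 1e-4)
  expect_equal(glmm$k, glm$k + 1)  # + variance component
})

test_that("GLMM recovers generative parameters on clustered data", {
  d <- glmm_sim(n_groups = 50, per = 20, seed = 6)
  fit <- fit_nb_glmm(d, "x")
  est <- fit$coefficients
  expect_lt(abs(est$estimate[est$term == "x"] - 0.5), 0.05)
  expect_lt(abs(sqrt(fit$sigma_alpha2) - 0.5), 0.15)
  expect_lt(abs(fit$theta - 5) / 5, 0.25)
  expect_equal(length(fit$conditional_modes), 50)
  expect_error(fit_nb_glmm(dplyr::mutate(d, reef_id = "R01"), "x"),
               "2 groups")
})

test_that("population predictions follow exp(X beta) exactly", {
  d <- nb_sim(40, log(10), seed = 7)
  engine_fit <- fit_nb_glm(d, "x")
  # force known coefficients; the engine is only consulted for the vcov
  fake <- engine_fit
  fake$coefficients$estimate <- c(log(10), log(2))
  expect_equal(predict_response(fake, tibble::tibble(x = 1))$fit, 20)
  expect_equal(predict_response(fake, tibble::tibble(x = 0))$fit, 10)

  # real fit: predictions at zero covariates equal exp(intercept)
  p0 <- predict_response(engine_fit, tibble::tibble(x = 0))
  expect_equal(p0$fit, exp(engine_fit$coefficients$estimate[1]))
  expect_gt(p0$se, 0)
  expect_error(predict_response(engine_fit, tibble::tibble(z = 1)), "x")
})

test_that("conditional predictions add known modes and fall back for new reefs", {
  d <- glmm_sim(seed = 8)
  fit <- fit_nb_glmm(d, "x")
  nd <- tibble::tibble(x = 0, reef_id = c("R01", "UNSEEN"))
  pop <- predict_response(fit, nd, mode = "population")
  con <- predict_response(fit, nd, mode = "conditional")
  expect_equal(con$fit[1] / pop$fit[1],
               exp(fit$conditional_modes[["R01"]]))
  expect_equal(con$fit[2], pop$fit[2])  # unseen reef: population fallback
  expect_error(predict_response(fit_nb_glm(d, "x"), nd, mode = "conditional"),
               "random")
})

test_that("predictions are invariant to design row order", {
  d <- glmm_sim(seed = 9)
  fit <- fit_nb_glmm(d, "x")
  nd <- tibble::tibble(x = seq(-1, 1, 0.5), reef_id = "R01")
  p <- predict_response(fit, nd)
  expect_equal(predict_response(fit, nd[5:1, ])$fit, rev(p$fit))
})

test_that("every candidate fit dominates the null it nests", {
  sys <- generate_system(small_ref_config())
  md <- model_data_for(sys, "G")
  ps <- build_predictor_set(md, all_predictors())
  null_fit <- fit_nb_glmm(ps$data, character(0))
  for (terms in model_set("GBR")$terms[c(2, 7, 10)]) {
    fit <- fit_nb_glmm(ps$data, terms)
    expect_gte(fit$loglik, null_fit$loglik - 1e-6)
  }
})

test_that("the Poisson dispersion statistic detects NB overdispersion", {
  # equidispersed: statistic near 1
  d_pois <- withr::with_seed(10, tibble::tibble(
    pooled_count = stats::rpois(500, 10)
  ))
  stat_pois <- dispersion_statistic(
    fit_poisson_test(d_pois, group = NULL)
  )
  expect_lt(abs(stat_pois - 1), 0.3)

  # NB2 with theta = 1, mu = 10: Pearson dispersion about 1 + mu/theta = 11
  d_nb <- withr::with_seed(11, tibble::tibble(
    pooled_count = rnbinom(500, mu = 10, size = 1)
  ))
  stat_nb <- dispersion_statistic(fit_poisson_test(d_nb, group = NULL))
  expect_gt(stat_nb, 5)

  # more dispersion (smaller theta) raises the statistic
  d_nb2 <- withr::with_seed(11, tibble::tibble(
    pooled_count = rnbinom(500, mu = 10, size = 4)
  ))
  stat_nb2 <- dispersion_statistic(fit_poisson_test(d_nb2, group = NULL))
  expect_gt(stat_nb, stat_nb2)

  # degenerate: constant response perfectly fitted
  d_const <- tibble::tibble(pooled_count = rep(5L, 20))
  expect_equal(dispersion_statistic(fit_poisson_test(d_const, group = NULL)),
               0)
})

test_that("fit objects tidy and glance cleanly", {
  d <- glmm_sim(seed = 12)
  fit <- fit_nb_glmm(d, "x", model_id = 3L)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "statistic", "p_value"))
  gl <- glance(fit)
  expect_equal(gl$model_id, 3L)
  expect_equal(gl$n, nrow(d))
  expect_equal(gl$aicc, aicc(fit))
})
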