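test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-50, k = 3, n = 100), 106.25)  # 100 + 6 + 24/96
  # correction vanishes for large n
  expect_lt(aicc(-50, k = 3, n = 1e6) - (100 + 6), 1e-4)
  expect_error(aicc(-50, k = 10, n = 11), "undefined")
})

test_that("Akaike weights are exact for a two-model set and normalize", {
  w <- akaike_weights(c(0, 2))
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(w[1], 1 / (1 + exp(-1)))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # invariance to constant shifts
  expect_equal(akaike_weights(c(1000, 1002)), w)
  expect_equal(akaike_weights(42), 1)
})

ranked_fixture <- function(group = "reef_id", seed = 21L) {
  sys <- generate_system(small_ref_config(seed = seed))
  md <- model_data_for(sys, "G")
  ps <- build_predictor_set(md, all_predictors())
  set <- model_set("GBR")[c(2, 7, 10, 12), ]
  fits <- purrr::map(seq_len(nrow(set)), function(i) {
    if (is.null(group)) {
      fit_nb_glm(ps$data, set$terms[[i]], model_id = set$model_id[i])
    } else {
      fit_nb_glmm(ps$data, set$terms[[i]], model_id = set$model_id[i])
    }
  })
  list(ranked = waicc_rank(fits), pset = ps, fits = fits)
}

test_that("ranking orders by weight with exact normalization", {
  rf <- ranked_fixture()
  ranked <- rf$ranked
  expect_equal(sum(ranked$waicc), 1, tolerance = 1e-12)
  expect_equal(ranked$delta_aicc[1], 0)
  expect_true(all(diff(ranked$waicc) <= 1e-12))
  expect_true(all(ranked$r2m <= ranked$r2c + 1e-12))
  expect_true(all(ranked$r2m >= 0 & ranked$r2c <= 1))
  expect_true(is.numeric(null_support(ranked)))
  expect_true(all(top_models(ranked) %in% ranked$model_id))
  # single model: weight 1
  single <- waicc_rank(rf$fits[1])
  expect_equal(single$waicc, 1)
})

test_that("ranking refuses fits on different responses", {
  sys <- generate_system(small_ref_config())
  md <- model_data_for(sys, "G")
  ps <- build_predictor_set(md, all_predictors())
  f1 <- fit_nb_glmm(ps$data, "sand", model_id = 5L)
  other <- dplyr::mutate(ps$data, pooled_count = pooled_count + 1L)
  f2 <- fit_nb_glmm(other, "mud", model_id = 6L)
  expect_error(waicc_rank(list(f1, f2)), "identical response")
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  # constructed fit with var_f = 1, var_alpha = 1, var_d = 2
  n <- 9
  x <- as.numeric(scale(1:n)) # sd exactly 1
  m <- 10
  theta <- 1 / (exp(2) - 1 - 1 / m)
  fake <- structure(list(
    coefficients = tibble::tibble(term = c("(Intercept)", "x"),
                                  estimate = c(0, 1), std_error = c(1, 1)),
    terms = "x", group = "reef_id", sigma_alpha2 = 1, theta = theta,
    response = "pooled_count",
    data = tibble::tibble(x = x, pooled_count = rep(m, n))
  ), class = "nb_fit")
  r2 <- r2_nakagawa(fake)
  expect_equal(r2$var_fixed, 1)
  expect_equal(r2$var_dist, 2)
  expect_equal(r2$r2m, 0.25)
  expect_equal(r2$r2c, 0.5)

  # null model: no fixed-effect variance
  sys <- generate_system(small_ref_config())
  md <- model_data_for(sys, "G")
  null_fit <- fit_nb_glmm(md, character(0))
  expect_equal(r2_nakagawa(null_fit)$r2m, 0)
  expect_gt(r2_nakagawa(null_fit)$r2c, 0)
  # trigamma variant shifts the distribution variance but keeps ordering
  r2t <- r2_nakagawa(null_fit, dist_variance = "trigamma")
  expect_lte(r2t$r2m, r2t$r2c)
})

test_that("deviance explained is 0% for the null GLM and positive for real fits", {
  rf <- ranked_fixture(group = NULL, seed = 22L)
  null_fit <- purrr::keep(rf$fits, ~ .x$model_id == 12)[[1]]
  expect_equal(deviance_explained(null_fit), 0, tolerance = 1e-8)
  best <- purrr::keep(rf$fits, ~ .x$model_id == 7)[[1]]
  expect_gt(deviance_explained(best), 0)
  glmm <- fit_nb_glmm(rf$pset$data, "sand")
  expect_error(deviance_explained(glmm), "GLM")
  expect_error(r2_nakagawa(purrr::keep(rf$fits, ~ .x$model_id == 7)[[1]]),
               "random")
})

test_that("effect sizes are weight-averaged standardized coefficients", {
  rf <- ranked_fixture()
  ranked <- rf$ranked
  es <- effect_sizes(ranked)
  expect_true(all(es$effect >= 0))

  # single-model set: effects equal that model's |coef| * sd(column)
  single <- waicc_rank(rf$fits[2])  # nutrients model
  es1 <- effect_sizes(single)
  fit <- rf$fits[[2]]
  for (p in fit$terms) {
    b <- fit$coefficients$estimate[fit$coefficients$term == p]
    expect_equal(es1$effect[es1$predictor == p],
                 abs(b) * sd(fit$data[[p]]))
  }

  # absence is exclusion, not a zero: a predictor unique to one model keeps
  # that model's standardized coefficient after weight renormalization,
  # whatever the other models' weights are
  m7 <- purrr::keep(attr(ranked, "fits"), ~ .x$model_id == 7)[[1]]
  b <- m7$coefficients$estimate[m7$coefficients$term == "no3_av"]
  expect_equal(es$effect[es$predictor == "no3_av"],
               abs(b) * sd(m7$data$no3_av))
  expect_equal(es$n_models[es$predictor == "no3_av"], 1L)
})

test_that("model-averaged predictions are the weighted mean of member predictions", {
  rf <- ranked_fixture()
  ranked <- rf$ranked
  nd <- rf$pset$data[1:6, ]
  avg <- model_average_predictions(ranked, nd)
  fits <- attr(ranked, "fits")
  hand <- Reduce(`+`, purrr::map2(fits, ranked$waicc, function(f, w) {
    w * predict_response(f, nd)$fit
  }))
  expect_equal(avg$fit, hand)
  expect_error(
    model_average_predictions(ranked, dplyr::select(nd, -"no3_av")),
    "unresolvable"
  )
})

test_that("a pure-noise predictor cannot reduce the log-likelihood", {
  sys <- generate_system(small_ref_config(seed = 23L))
  md <- model_data_for(sys, "G")
  md$noise <- withr::with_seed(1, rnorm(nrow(md)))
  ps <- build_predictor_set(md, c("sst_av", "noise"))
  base_fit <- fit_nb_glm(ps$data, "sst_av")
  noisy <- fit_nb_glm(ps$data, c("sst_av", "noise"))
  expect_gte(noisy$loglik, base_fit$loglik - 1e-6)
  expect_equal(noisy$k, base_fit$k + 1)  # the extra term is charged in AICc
})
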