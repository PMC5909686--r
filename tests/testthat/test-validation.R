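test_that("direct validation is exact in the perfect and degenerate limits", {
  obs <- c(3, 9, 5, 12, 7, 20)
  perfect <- suppressWarnings(direct_validation(obs, obs))
  expect_equal(perfect$r2_pct, 100)
  expect_lt(perfect$p_value, 1e-6)

  const <- direct_validation(obs, rep(4, 6))
  expect_true(is.na(const$r2_pct))
  expect_match(const$note, "constant")
})

test_that("validation against independent predictions behaves like the null", {
  res <- withr::with_seed(31, {
    purrr::map_dfr(1:100, function(i) {
      direct_validation(rnbinom(30, mu = 50, size = 3), rnorm(30))
    })
  })
  expect_lt(mean(res$r2_pct), 8)        # E[R2] = 1/(n-1) under the null
  expect_lt(mean(res$p_value < 0.05), 0.15)
  expect_gt(mean(res$p_value), 0.35)    # roughly uniform p-values
  expect_lt(mean(res$p_value), 0.65)
})

test_that("leave-one-out CV of the null model matches direct enumeration", {
  d <- withr::with_seed(32, tibble::tibble(
    pooled_count = rnbinom(10, mu = 20, size = 3)
  ))
  cv <- kfold_cv(d, character(0), group = NULL, k = 10, seed = 7)
  # intercept-only NB prediction is the training mean: enumerate by hand
  y <- d$pooled_count
  loo <- vapply(1:10, function(i) abs(y[i] - mean(y[-i])), numeric(1))
  expect_equal(sort(cv$per_fold$error), sort(loo), tolerance = 1e-8)
  expect_equal(cv$error_mean, mean(loo), tolerance = 1e-8)
})

test_that("cross-validation is reproducible and reef-stratified", {
  sys <- generate_system(small_ref_config())
  md <- model_data_for(sys, "G")
  ps <- build_predictor_set(md, all_predictors())
  cv1 <- kfold_cv(ps$data, "sst_av", k = 3, seed = 5)
  cv2 <- kfold_cv(ps$data, "sst_av", k = 3, seed = 5)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$error_mean, cv2$error_mean)
  expect_false(identical(cv1$folds, kfold_cv(ps$data, "sst_av", k = 3,
                                             seed = 6)$folds))
  expect_true(all(cv1$per_fold$error >= 0))
  # 3 sites per reef over 3 folds: every reef is represented in every
  # training set, so no fallback events
  expect_length(cv1$events, 0)
  tab <- table(ps$data$reef_id, cv1$folds)
  expect_true(all(tab == 1))
  gl <- glance(cv1)
  expect_equal(gl$pct_mean, cv1$pct_mean)
})

test_that("Moran's I matches a hand-evaluated double sum on four sites", {
  # four sites on a line; first band covers adjacent pairs only
  coords <- tibble::tibble(longitude = c(0, 0.01, 0.02, 0.03) / cos(0),
                           latitude = c(0, 0, 0, 0))
  z <- c(1, 1, -1, -1)
  # adjacent spacing ~1.1132 km; band width 1.5 km isolates adjacent pairs
  cor <- moran_correlogram(z, coords, band_width_km = 1.5, n_bands = 3)
  # I = (n/W) * sum w_ij z_i z_j / sum z_i^2 = (4/6) * 2/4 = 1/3
  expect_equal(cor$moran_i[1], 1 / 3, tolerance = 1e-12)
  expect_equal(cor$expected[1], -1 / 3, tolerance = 1e-12)
  expect_equal(cor$n_pairs[1], 3)
})

test_that("band Moran's I agrees with ape on an equal-degree layout", {
  # four sites on a square: every site has the same number of neighbours in
  # the adjacent-pair band, so row-standardized and binary weights coincide
  side_km <- 1.1132
  coords <- tibble::tibble(longitude = c(0, 0.01, 0, 0.01),
                           latitude = c(0, 0, 0.01, 0.01))
  z <- c(2, -1, 0.5, -1.5)
  cor <- moran_correlogram(z, coords, band_width_km = side_km * 1.1,
                           n_bands = 2)
  D <- as.matrix(stats::dist(cbind(coords$longitude, coords$latitude))) *
    111.32
  W <- (D > 0 & D <= side_km * 1.1) * 1
  oracle <- ape::Moran.I(z, W, alternative = "two.sided")
  expect_equal(cor$moran_i[1], oracle$observed, tolerance = 1e-10)
  expect_equal(cor$expected[1], oracle$expected)
})

test_that("the normality standard deviation matches a Monte-Carlo oracle", {
  coords <- withr::with_seed(71, tibble::tibble(
    longitude = runif(20, 146, 146.5), latitude = runif(20, -18.5, -18)
  ))
  D <- as.matrix(stats::dist(cbind(
    coords$longitude * 111.32 * cos(-18.25 * pi / 180),
    coords$latitude * 111.32
  )))
  bw <- as.numeric(quantile(D[upper.tri(D)], 0.25))
  W <- (D > 0 & D <= bw) * 1
  n <- 20
  sims <- withr::with_seed(72, vapply(1:20000, function(i) {
    z <- rnorm(n)
    z <- z - mean(z)
    (n / sum(W)) * drop(t(z) %*% W %*% z) / sum(z^2)
  }, numeric(1)))
  cor <- moran_correlogram(withr::with_seed(73, rnorm(n)), coords,
                           band_width_km = bw, n_bands = 2)
  expect_equal(cor$sd[1], sd(sims), tolerance = 0.03)
  expect_equal(cor$expected[1], mean(sims), tolerance = 0.02)
})

test_that("Moran's I is invariant to shifting and scaling residuals", {
  coords <- withr::with_seed(33, tibble::tibble(
    longitude = runif(25, 146, 147), latitude = runif(25, -19, -18)
  ))
  z <- withr::with_seed(34, rnorm(25))
  a <- moran_correlogram(z, coords, n_bands = 5)
  b <- moran_correlogram(10 + 3 * z, coords, n_bands = 5)
  expect_equal(a$moran_i, b$moran_i, tolerance = 1e-10)
  expect_error(moran_correlogram(rep(1, 25), coords), "variance")
})

test_that("permuted residuals sit at the null expectation", {
  coords <- withr::with_seed(35, tibble::tibble(
    longitude = runif(40, 146, 147), latitude = runif(40, -19, -18)
  ))
  z <- withr::with_seed(36, rnorm(40))
  cor <- withr::with_seed(37, moran_correlogram(sample(z), coords,
                                                n_bands = 6))
  expect_lt(abs(first_lag_moran(cor) - (-1 / 39)), 4 * cor$sd[1])
})

test_that("empty distance bands are skipped with a note", {
  # two tight clusters far apart: intermediate bands are empty
  coords <- tibble::tibble(
    longitude = c(146, 146.001, 146.002, 147, 147.001, 147.002),
    latitude = rep(-18, 6)
  )
  z <- c(1, -1, 2, -2, 1.5, -0.5)
  cor <- moran_correlogram(z, coords, band_width_km = 1, n_bands = 10)
  expect_gt(length(attr(cor, "bands_skipped")), 0)
  expect_true(all(diff(cor$d_min) > 0))
})

test_that("reef conditional modes absorb spatial autocorrelation in residuals", {
  cfg <- small_ref_config(seed = 38L)
  cfg$sigma_alpha <- 1
  sys <- generate_system(do.call(system_config, unclass(cfg)))
  md <- model_data_for(sys, "G")
  fit <- fit_nb_glmm(md, character(0))
  coords <- md[, c("longitude", "latitude")]
  i_pop <- first_lag_moran(moran_correlogram(
    residuals(fit, mode = "population"), coords
  ))
  i_cond <- first_lag_moran(moran_correlogram(
    residuals(fit, mode = "conditional"), coords
  ))
  expect_gt(i_pop, 0.2)   # reef clustering leaves strong first-lag structure
  expect_lt(i_cond, i_pop)
})

test_that("correlogram and CV plots build", {
  coords <- withr::with_seed(39, tibble::tibble(
    longitude = runif(20, 146, 147), latitude = runif(20, -19, -18)
  ))
  cor <- moran_correlogram(withr::with_seed(40, rnorm(20)), coords,
                           n_bands = 4)
  expect_s3_class(autoplot(cor), "ggplot")
  d <- withr::with_seed(41, tibble::tibble(
    pooled_count = rnbinom(24, mu = 20, size = 3),
    reef_id = rep(sprintf("R%d", 1:8), each = 3)
  ))
  cv <- kfold_cv(d, character(0), k = 3, seed = 1)
  expect_s3_class(autoplot(cv), "ggplot")
})
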