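test_that("iqr matches the interpolated-quantile definition", {
  expect_identical(iqr(1:101), 50)
  expect_identical(iqr(rep(7, 10)), 0)
  expect_error(iqr(c(1, 2, 3)), "at least 4")
  expect_error(iqr(c(1, 2, NA, NA, NA)), "at least 4")
  set.seed(31)
  x <- rnorm(20)
  expect_equal(iqr(x), brute_iqr(x), tolerance = 1e-12)
})

test_that("lag-mean exposure does the stated arithmetic", {
  expect_equal(lag_mean(c(1, 3, 5)), c(NA, 2, 4))
  expect_equal(lag_mean(rep(4, 6)), c(NA, rep(4, 5)))
  expect_equal(lag_mean(c(1, 2, 3, 4, 5, 6), c(-2L, -3L)),
               c(3.5, 4.5, 5.5, NA, NA, NA))
  expect_equal(instrument_exposure(c(1, 3, 5)), c(NA, 2, 4))
})

test_that("instrument features carry lags 0 and 1 with the first day NA", {
  p <- data.frame(pbl = c(700, 800, 900), wind_speed = c(5, 10, 15))
  f <- instrument_features(p)
  expect_identical(f$pbl_lag1, c(NA, 700, 800))
  expect_identical(f$wind_lag1, c(NA, 5, 10))
  expect_true(all(is.na(f[1, c("pbl_lag1", "wind_lag1")])))
})

test_that("a noiseless linear signal is recovered almost perfectly", {
  set.seed(1)
  X <- data.frame(a = rnorm(400), b = rnorm(400),
                  c = rnorm(400), d = rnorm(400))
  y <- 2 * X$a - X$b + 0.5 * X$c
  fit <- fit_instrument(X, y, seed = 3)
  expect_gt(fit$cv_r2, 0.99)
  expect_false(fit$overfit_flag)
})

test_that("pure noise raises the weak-instrument guard", {
  set.seed(2)
  X <- data.frame(a = rnorm(400), b = rnorm(400),
                  c = rnorm(400), d = rnorm(400))
  err <- tryCatch(fit_instrument(X, rnorm(400), seed = 3),
                  error = function(e) e)
  expect_s3_class(err, "pbliv_weak_instrument")
  expect_lte(err$cv_r2, 0.05)
})

test_that("permuting the target against features destroys the instrument", {
  sim <- generate_panel(sim_config(n_days = 1096, seed = 23))
  s <- assign_strata(sim$panel)
  r <- as.numeric(orthogonalize(sim$panel$pm25, s))
  set.seed(99)
  r_perm <- c(NA, sample(r[-1]))
  err <- tryCatch(
    fit_instrument(instrument_features(sim$panel), r_perm,
                   grid = svr_grid_reduced(), seed = 23),
    error = function(e) e)
  expect_s3_class(err, "pbliv_weak_instrument")
  expect_lte(err$cv_r2, 0.05)
})

test_that("the seeded fold partition makes the fit deterministic", {
  sim <- generate_panel(sim_config(n_days = 1096, seed = 29))
  s <- assign_strata(sim$panel)
  r <- orthogonalize(sim$panel$pm25, s)
  f <- instrument_features(sim$panel)
  g <- svr_grid(cost = c(1, 10), gamma = 0.25)
  fit1 <- fit_instrument(f, r, grid = g, seed = 5)
  fit2 <- fit_instrument(f, r, grid = g, seed = 5)
  expect_identical(fit1$hyperparameters, fit2$hyperparameters)
  expect_identical(fit1$instrument, fit2$instrument)
  expect_identical(fit1$iqr, fit2$iqr)
})

test_that("CV R2 tracks the generator's oracle first-stage R2", {
  sim <- generate_panel(sim_config(n_days = 1826, seed = 41))
  s <- assign_strata(sim$panel)
  r <- orthogonalize(sim$panel$pm25, s)
  fit <- fit_instrument(instrument_features(sim$panel), r,
                        grid = svr_grid(cost = c(1, 10),
                                        gamma = c(0.25, 1)),
                        seed = 41)
  r2_oracle <- oracle_first_stage_r2(sim, s)
  expect_lt(abs(fit$cv_r2 - r2_oracle), 0.1)
  # first stage predicts exposure, not noise: training close to CV
  expect_gte(fit$train_r2, fit$cv_r2 - 0.05)
  expect_false(fit$overfit_flag)
})

test_that("the fitted instrument is uncorrelated with the confounder", {
  sim <- generate_panel(sim_config(n_days = 3652, seed = 43))
  s <- assign_strata(sim$panel)
  r <- orthogonalize(sim$panel$pm25, s)
  fit <- fit_instrument(instrument_features(sim$panel), r,
                        grid = svr_grid_reduced(), seed = 43)
  expo <- instrument_exposure(fit)
  ok <- !is.na(expo)
  expect_lt(abs(cor(expo[ok], sim$truth$U[ok])), 2 / sqrt(sum(ok)))
})

test_that("exposure IQR equals the sort-based oracle on a seeded panel", {
  sim <- generate_panel(sim_config(n_days = 1096, seed = 47))
  s <- assign_strata(sim$panel)
  r <- orthogonalize(sim$panel$pm25, s)
  fit <- fit_instrument(instrument_features(sim$panel), r,
                        grid = svr_grid_reduced(), seed = 47)
  expect_equal(fit$iqr, brute_iqr(fit$exposure), tolerance = 1e-12)
})

test_that("too few aligned days are rejected", {
  X <- data.frame(a = rnorm(100), b = rnorm(100),
                  c = rnorm(100), d = rnorm(100))
  expect_error(fit_instrument(X, rnorm(100)), "at least 200")
})
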