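test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_days = 365), "730")
  expect_error(sim_config(overdispersion = 0.9), "overdispersion")
  expect_error(sim_config(pbl_mean = -5), "positive")
  expect_error(sim_config(emission_mean = 0), "positive")
  # null causal/confounding scenarios must be expressible
  cfg <- sim_config(theta = 0, gamma_confound = 0, kappa_confound = 0)
  expect_identical(cfg$theta, 0)
})

test_that("a fixed seed reproduces the panel and oracle bit-identically", {
  cfg <- sim_config(n_days = 730, seed = 99)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(oracle_instrument(a$truth), oracle_instrument(b$truth))
})

test_that("confounded flag reflects whether both confounder arms are active", {
  s1 <- generate_panel(sim_config(n_days = 730, seed = 1))
  s2 <- generate_panel(sim_config(n_days = 730, seed = 1,
                                  gamma_confound = 0))
  s3 <- generate_panel(sim_config(n_days = 730, seed = 1,
                                  kappa_confound = 0))
  expect_true(s1$truth$confounded)
  expect_false(s2$truth$confounded)
  expect_false(s3$truth$confounded)
})

test_that("true per-IQR effect is the exact transform of theta", {
  sim <- generate_panel(sim_config(n_days = 1096, seed = 5))
  expect_equal(sim$truth$theta_per_iqr_true,
               100 * (exp(sim$truth$theta_true * sim$truth$oracle_iqr) - 1))
})

test_that("null scenario: deaths uncorrelated with pollution", {
  sim <- generate_panel(sim_config(
    n_days = 3650, seed = 17, theta = 0, gamma_confound = 0,
    mortality_season_amp = 0, temp_mortality_effects = rep(0, 10)
  ))
  expect_lt(abs(cor(sim$panel$deaths, sim$panel$pm25)), 0.05)
})

test_that("default city reproduces the target daily moments within 15%", {
  sim <- generate_panel(sim_config(n_days = 3652, seed = 7))
  p <- sim$panel
  within15 <- function(x, target) abs(x - target) / target < 0.15
  expect_true(within15(mean(p$deaths), 55.8))
  expect_true(within15(sd(p$deaths), 9.5))
  expect_true(within15(mean(p$pm25), 9.8))
  expect_true(within15(sd(p$pm25), 5.8))
  expect_true(within15(mean(p$pbl), 770))
  expect_true(within15(sd(p$pbl), 356))
  expect_true(within15(mean(p$wind_speed), 9.6))
  expect_true(within15(sd(p$wind_speed), 3.2))
  expect_true(within15(mean(p$temperature), 10.8))
  expect_true(within15(sd(p$temperature), 9.4))
})

test_that("correlation signs match the ventilation mechanism", {
  sim <- generate_panel(sim_config(n_days = 3652, seed = 7))
  p <- sim$panel
  for (pol in c("pm25", "bc", "no2")) {
    expect_lt(cor(p[[pol]], p$pbl), 0)
    expect_lt(cor(p[[pol]], p$wind_speed), 0)
  }
  expect_gt(cor(p$pbl, p$wind_speed), 0)
  expect_gt(cor(p$pm25, p$bc), 0)
  expect_gt(cor(p$pm25, p$no2), 0)
})

test_that("death counts are overdispersed toward the configured phi", {
  sim <- generate_panel(sim_config(
    n_days = 3652, seed = 21, theta = 0, gamma_confound = 0,
    mortality_season_amp = 0, temp_mortality_effects = rep(0, 10),
    overdispersion = 1.3
  ))
  ratio <- var(sim$panel$deaths) / mean(sim$panel$deaths)
  expect_gte(ratio, 1)
  expect_gt(ratio, 1.15)
  expect_lt(ratio, 1.45)
})

test_that("oracle instrument is independent of the confounder", {
  sim <- generate_panel(sim_config(n_days = 10958, seed = 3))
  expect_lt(abs(cor(oracle_instrument(sim$truth), sim$truth$U)), 0.03)
})

test_that("with kappa = 0 the oracle R2 equals the dilution variance share", {
  sim <- generate_panel(sim_config(n_days = 10958, seed = 13,
                                   kappa_confound = 0))
  r2_fit <- oracle_first_stage_r2(sim)
  # independent route: population identity R2 = var(oracle) / var(pollutant)
  # (the dilution term's share of total pollutant variance)
  r2_decomp <- var(sim$truth$oracle) / var(sim$panel$pm25)
  expect_equal(r2_fit, r2_decomp, tolerance = 0.02)
})
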