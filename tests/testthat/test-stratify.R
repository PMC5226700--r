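test_that("ten calendar years yield 120 month-year strata", {
  # 2000-01-01 through 2009-12-31 is 3,653 days (three leap years)
  sim <- generate_panel(sim_config(n_days = 3653, seed = 2))
  s <- assign_strata(sim$panel)
  expect_identical(nlevels(s$month_year), 120L)
})

test_that("deciles are balanced for distinct temperatures", {
  set.seed(8)
  p <- data.frame(date = seq(as.Date("2000-01-01"), by = "day",
                             length.out = 3650),
                  temperature = sample(seq(-15, 32, length.out = 3650)))
  s <- assign_strata(p)
  expect_identical(unname(as.integer(table(s$temp_decile))), rep(365L, 10))
  expect_length(attr(s, "cutpoints"), 9L)
})

test_that("ties at a cutpoint fall in the lower decile", {
  # 21 values 1..21: type-7 decile cutpoints land exactly on 3, 5, ..., 19
  p <- data.frame(date = seq(as.Date("2000-01-01"), by = "day",
                             length.out = 21),
                  temperature = 1:21)
  s <- suppressWarnings(assign_strata(p))
  expect_equal(attr(s, "cutpoints"), seq(3, 19, by = 2))
  expect_identical(s$temp_decile[p$temperature == 3], 1L)   # on the cut
  expect_identical(s$temp_decile[p$temperature == 4], 2L)   # just above
  expect_identical(s$temp_decile[p$temperature == 19], 9L)  # on the cut
  expect_identical(s$temp_decile[p$temperature == 21], 10L)
})

test_that("degenerate temperature collapses to one decile with a warning", {
  p <- data.frame(date = seq(as.Date("2000-01-01"), by = "day",
                             length.out = 40),
                  temperature = rep(5, 40))
  expect_warning(s <- assign_strata(p), "tied temperature quantiles")
  expect_identical(unique(s$temp_decile), 1L)
})

test_that("all-missing temperature and unsorted dates are rejected", {
  p <- data.frame(date = seq(as.Date("2000-01-01"), by = "day",
                             length.out = 10),
                  temperature = rep(NA_real_, 10))
  expect_error(assign_strata(p), "temperatures missing")
  p2 <- data.frame(date = as.Date(c("2000-01-02", "2000-01-01")),
                   temperature = c(1, 2))
  expect_error(assign_strata(p2), "strictly increasing")
})

test_that("short month-year strata trigger a warning", {
  sim <- generate_panel(sim_config(n_days = 735, seed = 4))
  expect_warning(assign_strata(sim$panel), "< 5 days")
})

test_that("orthogonalization removes additive stratum structure", {
  sim <- generate_panel(sim_config(n_days = 1096, seed = 11))
  s <- suppressWarnings(assign_strata(sim$panel))
  r <- orthogonalize(sim$panel$pm25, s)

  # marginal residual means vanish within every level of each factor
  expect_lt(max(abs(tapply(as.numeric(r), s$month_year, mean))), 1e-8)
  expect_lt(max(abs(tapply(as.numeric(r), s$temp_decile, mean))), 1e-8)

  # residuals orthogonal to every stratum indicator
  X <- stats::model.matrix(~ month_year + factor(temp_decile), data = s)
  expect_lt(max(abs(cor(as.numeric(r), X[, -1]))), 1e-8)

  # idempotence
  r2 <- orthogonalize(as.numeric(r), s)
  expect_equal(as.numeric(r2), as.numeric(r), tolerance = 1e-10)
})

test_that("constant series and single-stratum panels degrade gracefully", {
  p <- toy_two_by_two_panel()
  s <- suppressWarnings(assign_strata(p))
  r <- orthogonalize(rep(3.5, 30), s)
  expect_equal(as.numeric(r), rep(0, 30), tolerance = 1e-12)

  one <- data.frame(date = seq(as.Date("2001-01-01"), by = "day",
                               length.out = 20),
                    temperature = rep(1, 20))
  s1 <- suppressWarnings(assign_strata(one))
  y <- rnorm(20)
  expect_equal(as.numeric(orthogonalize(y, s1)), y - mean(y),
               tolerance = 1e-12)
})

test_that("toy two-by-two fit matches the normal-equations oracle", {
  p <- toy_two_by_two_panel()
  s <- suppressWarnings(assign_strata(p))
  expect_identical(length(unique(s$temp_decile)), 2L)
  r <- orthogonalize(p$y, s)
  oracle <- brute_two_way_residuals(p$y, s$month_year,
                                    factor(s$temp_decile))
  expect_equal(as.numeric(r), oracle, tolerance = 1e-8)
})

test_that("missing values are dropped and counted", {
  sim <- generate_panel(sim_config(n_days = 730, seed = 12))
  s <- assign_strata(sim$panel)
  x <- sim$panel$pm25
  x[c(5, 50, 500)] <- NA
  r <- orthogonalize(x, s)
  expect_identical(attr(r, "n_dropped"), 3L)
  expect_true(all(is.na(as.numeric(r)[c(5, 50, 500)])))
})
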