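# Independent oracles used across tests.

# Linear-interpolation quantile computed directly from sorted order
# statistics (position h = 1 + (n-1)p), independent of stats::quantile.
brute_quantile <- function(x, p) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, n)] - x[lo])
}

brute_iqr <- function(x) brute_quantile(x, 0.75) - brute_quantile(x, 0.25)

# Two-way additive least squares by explicit normal equations.
brute_two_way_residuals <- function(y, f1, f2) {
  X <- cbind(1,
             stats::model.matrix(~ f1)[, -1, drop = FALSE],
             stats::model.matrix(~ f2)[, -1, drop = FALSE])
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# Small panel with two month-year strata and two temperature groups, known
# additive structure plus noise.
toy_two_by_two_panel <- function(seed = 42) {
  set.seed(seed)
  dates <- seq(as.Date("2001-01-15"), by = "day", length.out = 30)
  month_fx <- ifelse(format(dates, "%m") == "01", 0, 1.5)
  temp <- rep(c(0, 10), length.out = 30)
  temp_fx <- ifelse(temp > 5, -0.8, 0)
  y <- 5 + month_fx + temp_fx + rnorm(30, sd = 0.3)
  data.frame(date = dates, temperature = temp, y = y)
}
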