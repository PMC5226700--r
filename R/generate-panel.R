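# Synthetic-city generator: daily meteorology, pollution and mortality with
# a known causal effect and an explicit unmeasured-confounder pathway.

# Stationary AR(1) with marginal SD `sd`; first value drawn from the
# stationary distribution.
ar1_series <- function(n, rho, sd = 1) {
  if (rho == 0) return(rnorm(n, 0, sd))
  innov <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

# Mean-one lognormal multiplicative noise.
lognorm_noise <- function(n, sigma) exp(rnorm(n, 0, sigma) - sigma^2 / 2)

# Trailing moving average over `lags` (non-negative = past, negative = lead).
# NA wherever any required day falls outside the series.
shift_series <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  if (lag > 0) c(rep(NA_real_, lag), x[seq_len(n - lag)])
  else c(x[-seq_len(-lag)], rep(NA_real_, -lag))
}

#' Mean of a series over a set of lags
#'
#' `lag_mean(x, c(0, 1))[t]` is `(x[t] + x[t-1]) / 2`, the conventional
#' two-day mean exposure; negative lags are leads (`x[t - lag] = x[t + k]`).
#' Days for which any required lag falls outside the series are `NA`.
#'
#' @param x Numeric series.
#' @param lags Integer vector of lags (non-negative past, negative future).
#' @return Numeric series of the same length as `x`.
#' @export
#' @examples
#' lag_mean(c(1, 3, 5), c(0, 1)) # NA 2 4
lag_mean <- function(x, lags = c(0L, 1L)) {
  m <- vapply(lags, function(L) shift_series(x, L), numeric(length(x)))
  rowMeans(matrix(m, nrow = length(x)))
}

# Ventilation (dilution) factor: the box-model rationale that local
# concentrations scale with 1 / (mixing depth x horizontal transport).
# Offsets represent mixing that persists even on shallow-PBL, calm days
# (residual layer, urban roughness turbulence); without them daily 1/v has
# an unphysically heavy tail.
ventilation <- function(pbl, wind, cfg) {
  ((pmax(pbl, 100) + cfg$vent_pbl_offset) /
     (cfg$pbl_mean + cfg$vent_pbl_offset))^cfg$vent_exp_pbl *
    ((pmax(wind, 1) + cfg$vent_wind_offset) /
       (cfg$wind_mean + cfg$vent_wind_offset))^cfg$vent_exp_wind
}

#' Simulate a daily city panel with known causal structure
#'
#' Generates `n_days` of daily temperature, PBL height, wind speed,
#' pollutant concentrations (PM2.5, BC, NO2) and death counts from a
#' mechanistic model in which local pollution is local emissions divided by
#' a ventilation factor (increasing in PBL height and wind speed) plus an
#' autocorrelated transported background. An unmeasured AR(1) confounder U
#' raises both emissions (`kappa_confound`) and log mortality
#' (`gamma_confound`), so that naive regression of deaths on pollution is
#' biased while meteorology-driven variation in pollution remains clean.
#' Deaths are gamma-mixed Poisson (Var = phi * mu) with log-mean
#' `log(baseline) + season + temperature-decile effects +
#' theta * mean(pollutant, lags 0,1) + gamma * U`.
#'
#' @param config A [sim_config()].
#' @return An object of class `city_sim`: a list with
#'   \describe{
#'     \item{panel}{data.frame with columns `date, deaths, pm25, bc, no2,
#'       pbl, wind_speed, temperature`.}
#'     \item{truth}{`sim_truth` object: `theta_true`, `theta_per_iqr_true`
#'       (percent per IQR of the lag-averaged oracle instrument, exactly
#'       `100*(exp(theta*IQR)-1)`), `confounded`, the latent series
#'       (`U`, `local`, `transported`, `ventilation`, `oracle`,
#'       `oracle_exposure`), `oracle_iqr`, and the `config`.}
#'   }
#' @export
#' @examples
#' sim <- generate_panel(sim_config(n_days = 730, seed = 7))
#' summary(sim$panel$deaths)
generate_panel <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_days
  set.seed(cfg$seed)

  dates <- seq(as.Date("2000-01-01"), by = "day", length.out = n)
  yday <- as.POSIXlt(dates)$yday + 1
  # +1 in mid-January, -1 in mid-July
  seas <- cos(2 * pi * (yday - 15) / 365.25)
  # month-level seasonal term (evaluated at mid-month): the mortality
  # seasonality the analysis model absorbs with month-by-year indicators
  mid_month <- as.POSIXlt(as.Date(format(dates, "%Y-%m-15")))$yday + 1
  seas_month <- cos(2 * pi * (mid_month - 15) / 365.25)

  ## temperature: seasonal sinusoid + persistent AR(1) weather noise
  temperature <- cfg$temp_mean - cfg$temp_amplitude * seas +
    ar1_series(n, 0.8, 4.5)

  ## meteorology: shared synoptic factor ties PBL height and wind speed;
  ## both run higher in winter (storm-driven mixing), matching the negative
  ## temperature correlations seen in reanalysis daily means
  synoptic <- ar1_series(n, 0.5, 1)
  r <- cfg$pbl_wind_cor
  pbl_z <- sqrt(r) * synoptic + sqrt(1 - r) * rnorm(n)
  wind_z <- sqrt(r) * synoptic + sqrt(1 - r) * rnorm(n)
  if (cfg$instrument_confound > 0) {
    # invalid-instrument scenario: persistent confounder W loads on the
    # meteorology at all lags and on mortality below
    W <- ar1_series(n, 0.9, 1)
    pbl_z <- pbl_z - cfg$instrument_confound * W
    wind_z <- wind_z - cfg$instrument_confound * W
  } else {
    W <- numeric(n)
  }
  pbl_seas_amp <- 120
  pbl_resid_sd <- sqrt(max(cfg$pbl_sd^2 - pbl_seas_amp^2 / 2, 1))
  pbl <- pmax(cfg$pbl_mean + pbl_seas_amp * seas + pbl_resid_sd * pbl_z, 100)
  wind_seas_amp <- 0.8
  wind_resid_sd <- sqrt(max(cfg$wind_sd^2 - wind_seas_amp^2 / 2, 0.01))
  wind <- pmax(cfg$wind_mean + wind_seas_amp * seas + wind_resid_sd * wind_z,
               1)

  ## unmeasured confounder and pollution components
  U <- ar1_series(n, cfg$confounder_rho, 1)
  vent <- ventilation(pbl, wind, cfg)
  emissions <- cfg$emission_mean * lognorm_noise(n, cfg$emission_sigma) +
    cfg$kappa_confound * U
  emissions <- pmax(emissions, 0.05 * cfg$emission_mean)
  local <- emissions / vent
  transported <- cfg$background_mean *
    exp(ar1_series(n, cfg$background_ar1, cfg$background_sigma) -
          cfg$background_sigma^2 / 2)
  pm25 <- local + transported

  ## co-emitted tracers: sign structure only (local share differs by
  ## pollutant; BC mostly local traffic, NO2 local combustion)
  bc <- pmax(0.08 * local + 0.24 * lognorm_noise(n, 0.5) +
               rnorm(n, 0, 0.08), 0.05)
  no2 <- pmax(1.1 * local + 12 * lognorm_noise(n, 0.18) + rnorm(n, 0, 1.5),
              1)

  ## oracle instrument: the component of pollution explained by same-day
  ## meteorology under the true equations, E[emissions]/v; independent of U
  oracle <- cfg$emission_mean / vent
  oracle_exposure <- lag_mean(oracle, cfg$effect_lags)
  oracle_exposure[is.na(oracle_exposure)] <- oracle[is.na(oracle_exposure)]
  oracle_iqr <- iqr(oracle_exposure)

  ## mortality
  x <- lag_mean(pm25, cfg$effect_lags)
  x[is.na(x)] <- pm25[is.na(x)] # leading days: use what exists
  dec <- findInterval(temperature,
                      quantile(temperature, seq(0.1, 0.9, by = 0.1),
                               type = 7),
                      left.open = TRUE) + 1L
  lp <- cfg$mortality_season_amp * seas_month +
    cfg$temp_mortality_effects[dec] +
    cfg$theta * x +
    cfg$gamma_confound * U +
    cfg$instrument_confound_mort * W * (cfg$instrument_confound > 0) +
    cfg$direct_effect * (oracle_exposure - mean(oracle_exposure))
  mu <- cfg$deaths_baseline * exp(lp - mean(lp))
  phi <- cfg$overdispersion
  if (phi > 1) {
    shape <- mu / (phi - 1)
    mu_mix <- mu * rgamma(n, shape = shape, rate = shape)
  } else {
    mu_mix <- mu
  }
  deaths <- rpois(n, mu_mix)

  panel <- data.frame(
    date = dates, deaths = deaths, pm25 = pm25, bc = bc, no2 = no2,
    pbl = pbl, wind_speed = wind, temperature = temperature
  )
  truth <- structure(list(
    theta_true = cfg$theta,
    theta_per_iqr_true = 100 * expm1(cfg$theta * oracle_iqr),
    confounded = cfg$gamma_confound != 0 && cfg$kappa_confound != 0,
    U = U, local = local, transported = transported,
    ventilation = vent, oracle = oracle,
    oracle_exposure = oracle_exposure, oracle_iqr = oracle_iqr,
    W = W, seed = cfg$seed, config = cfg
  ), class = "sim_truth")
  structure(list(panel = panel, truth = truth), class = "city_sim")
}

#' Oracle instrument of a simulated city
#'
#' Returns the generator's own first-stage truth: the component of the
#' pollutant concentration explained by same-day meteorology (mean emissions
#' divided by the ventilation factor), a deterministic function of PBL
#' height and wind speed that is independent of the unmeasured confounder by
#' construction. Used to validate the fitted instrument.
#'
#' @param truth A `sim_truth` object from [generate_panel()].
#' @return Numeric per-day series.
#' @export
oracle_instrument <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  truth$oracle
}

#' Oracle first-stage R-squared
#'
#' Squared correlation between the oracle instrument and the pollutant
#' series, optionally after orthogonalizing both to strata — the share of
#' (residual) pollutant variance that a perfect first stage could explain.
#' The cross-validated R-squared of [fit_instrument()] should approach this
#' from below.
#'
#' @param sim A `city_sim` object.
#' @param strata Optional [assign_strata()] result; when given, both series
#'   are residualized first.
#' @param pollutant Pollutant column name (default `"pm25"`).
#' @return Scalar R-squared.
#' @export
oracle_first_stage_r2 <- function(sim, strata = NULL, pollutant = "pm25") {
  stopifnot(inherits(sim, "city_sim"))
  a <- sim$panel[[pollutant]]
  z <- sim$truth$oracle
  if (!is.null(strata)) {
    a <- orthogonalize(a, strata)
    z <- orthogonalize(z, strata)
  }
  cor(a, z, use = "complete.obs")^2
}

#' @export
print.city_sim <- function(x, ...) {
  cat("<city_sim>", nrow(x$panel), "days,",
      format(min(x$panel$date)), "to", format(max(x$panel$date)), "\n")
  cat("  true effect:", signif(x$truth$theta_per_iqr_true, 3),
      "% per oracle-instrument IQR (",
      signif(x$truth$oracle_iqr, 3), "units )\n")
  cat("  confounded:", x$truth$confounded, "\n")
  invisible(x)
}
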