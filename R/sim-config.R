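#' Reference IQR of the lag-averaged oracle instrument
#'
#' Interquartile range (in instrument units, ~ug/m3 of locally generated
#' PM2.5) of the two-day mean of the oracle instrument under the default
#' city calibration, estimated once from a long (100-year) simulation.
#' Used by [sim_config()] to translate a target percent-per-IQR effect into
#' the per-unit log rate ratio `theta`.
#'
#' @keywords internal
.REF_ORACLE_IQR <- 3.26

#' Configuration for the synthetic-city generator
#'
#' Defines the generative model of [generate_panel()]. Defaults are
#' calibrated so that a simulated city reproduces the daily scale of a
#' mid-sized U.S. metropolitan area over a 2000-2009 study period
#' (deaths 55.8 +/- 9.5 per day, PM2.5 9.8 +/- 5.8
#' ug/m3, PBL height 770 +/- 356 m, wind speed 9.6 +/- 3.2 knots,
#' temperature 10.8 +/- 9.4 C) and the sign pattern of their correlations
#' (pollution negatively correlated with PBL height and wind speed, PBL and
#' wind positively correlated), with an active unmeasured-confounder
#' pathway so that naive regression of deaths on pollution is biased while
#' the instrument is not.
#'
#' @param n_days Number of consecutive days to simulate; at least 730 so
#'   that month-by-year strata are nondegenerate.
#' @param seed Integer seed; every random draw in [generate_panel()] derives
#'   from it.
#' @param theta True causal log rate ratio of daily deaths per unit (ug/m3)
#'   of the two-day mean pollutant concentration. The default corresponds to
#'   `percent_per_iqr` via the reference oracle-instrument IQR.
#' @param percent_per_iqr Convenience alternative to `theta`: target percent
#'   increase in daily deaths per reference IQR increase of the lag-averaged
#'   oracle instrument (default 0.90, the scale of effect the pipeline is
#'   designed to detect). Ignored when `theta` is given.
#' @param gamma_confound Effect of the unmeasured confounder U (standard
#'   normal AR(1)) on log daily mortality.
#' @param kappa_confound Effect of U on local emissions (ug/m3-equivalent
#'   per SD of U). With both confounder parameters nonzero, pollution and
#'   mortality share a common cause that is invisible to the outcome model.
#' @param emission_mean Mean local emission scale (ug/m3-equivalent at
#'   average ventilation).
#' @param emission_sigma Log-scale SD of day-to-day emission variation.
#' @param background_mean Mean transported (regional) pollution, ug/m3.
#' @param background_ar1 Lag-1 autocorrelation of the transported component.
#' @param background_sigma Log-scale SD of the transported component.
#' @param temp_mean,temp_amplitude Mean and seasonal amplitude of daily
#'   temperature, degrees C.
#' @param pbl_mean,pbl_sd Mean and SD of daily PBL height, m.
#' @param wind_mean,wind_sd Mean and SD of daily wind speed, knots.
#' @param pbl_wind_cor Target correlation between PBL height and wind speed
#'   (shared synoptic ventilation factor).
#' @param vent_exp_pbl,vent_exp_wind Exponents a, b of the ventilation
#'   (dilution) function
#'   v = ((PBL+c1)/(PBL_mean+c1))^a * ((wind+c2)/(wind_mean+c2))^b.
#' @param vent_pbl_offset,vent_wind_offset The offsets c1 (m) and c2
#'   (knots): mixing that persists on shallow-PBL, calm days (residual
#'   layer, urban roughness), bounding the dilution tail.
#' @param confounder_rho AR(1) coefficient of the unmeasured confounder U.
#' @param deaths_baseline Expected daily deaths at average covariates.
#' @param overdispersion Variance inflation phi >= 1 of daily deaths
#'   (gamma-mixed Poisson, Var = phi * mu).
#' @param mortality_season_amp Amplitude of the seasonal (winter-excess)
#'   term on log mortality; resolved at month level, the granularity the
#'   analysis model's month-by-year indicators absorb.
#' @param temp_mortality_effects Length-10 vector of temperature-decile
#'   effects on log mortality (cold and heat excess at the extremes).
#' @param effect_lags Integer lags over which the true pollutant effect is
#'   averaged; default `c(0, 1)`, mirroring the analysis model.
#' @param instrument_confound Loading of a persistent confounder W on PBL
#'   height and wind speed (an *invalid-instrument* scenario; 0 disables).
#' @param instrument_confound_mort Effect of W on log mortality when
#'   `instrument_confound > 0`.
#' @param direct_effect Direct effect of the (lag-averaged, centered) oracle
#'   instrument on log mortality, bypassing pollution — an
#'   exclusion-restriction violation scenario; 0 disables.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_panel()]
#' @export
#' @examples
#' cfg <- sim_config(n_days = 730, seed = 1)
#' cfg$theta
sim_config <- function(n_days = 3652L,
                       seed = 1L,
                       theta = NULL,
                       percent_per_iqr = 0.90,
                       gamma_confound = 0.05,
                       kappa_confound = 2,
                       emission_mean = 4.4,
                       emission_sigma = 0.40,
                       background_mean = 4.2,
                       background_ar1 = 0.6,
                       background_sigma = 0.50,
                       temp_mean = 10.8,
                       temp_amplitude = 11.5,
                       pbl_mean = 770,
                       pbl_sd = 356,
                       wind_mean = 9.6,
                       wind_sd = 3.2,
                       pbl_wind_cor = 0.55,
                       vent_exp_pbl = 1,
                       vent_exp_wind = 1,
                       vent_pbl_offset = 250,
                       vent_wind_offset = 4,
                       confounder_rho = 0.3,
                       deaths_baseline = 55.8,
                       overdispersion = 1.3,
                       mortality_season_amp = 0.06,
                       temp_mortality_effects = c(0.035, 0.015, 0.005, 0, 0,
                                                  0, 0, 0.005, 0.015, 0.035),
                       effect_lags = c(0L, 1L),
                       instrument_confound = 0,
                       instrument_confound_mort = 0.05,
                       direct_effect = 0) {
  if (is.null(theta)) {
    theta <- log1p(percent_per_iqr / 100) / .REF_ORACLE_IQR
  }
  cfg <- list(
    n_days = as.integer(n_days), seed = as.integer(seed), theta = theta,
    gamma_confound = gamma_confound, kappa_confound = kappa_confound,
    emission_mean = emission_mean, emission_sigma = emission_sigma,
    background_mean = background_mean, background_ar1 = background_ar1,
    background_sigma = background_sigma,
    temp_mean = temp_mean, temp_amplitude = temp_amplitude,
    pbl_mean = pbl_mean, pbl_sd = pbl_sd,
    wind_mean = wind_mean, wind_sd = wind_sd,
    pbl_wind_cor = pbl_wind_cor,
    vent_exp_pbl = vent_exp_pbl, vent_exp_wind = vent_exp_wind,
    vent_pbl_offset = vent_pbl_offset, vent_wind_offset = vent_wind_offset,
    confounder_rho = confounder_rho,
    deaths_baseline = deaths_baseline, overdispersion = overdispersion,
    mortality_season_amp = mortality_season_amp,
    temp_mortality_effects = temp_mortality_effects,
    effect_lags = as.integer(effect_lags),
    instrument_confound = instrument_confound,
    instrument_confound_mort = instrument_confound_mort,
    direct_effect = direct_effect
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_days < 730L) {
    stop("n_days must be >= 730 (two years) so month-by-year strata are ",
         "nondegenerate; got ", cfg$n_days, call. = FALSE)
  }
  if (cfg$overdispersion < 1) {
    stop("overdispersion must be >= 1 (quasi-Poisson variance inflation)",
         call. = FALSE)
  }
  scales <- c(emission_mean = cfg$emission_mean,
              emission_sigma = cfg$emission_sigma,
              background_mean = cfg$background_mean,
              background_sigma = cfg$background_sigma,
              temp_amplitude = cfg$temp_amplitude,
              pbl_mean = cfg$pbl_mean, pbl_sd = cfg$pbl_sd,
              wind_mean = cfg$wind_mean, wind_sd = cfg$wind_sd,
              deaths_baseline = cfg$deaths_baseline)
  bad <- names(scales)[!is.finite(scales) | scales <= 0]
  if (length(bad)) {
    stop("scale parameters must be positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (cfg$background_ar1 < 0 || cfg$background_ar1 >= 1 ||
      cfg$confounder_rho < 0 || cfg$confounder_rho >= 1) {
    stop("autocorrelation parameters must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$pbl_wind_cor <= 0 || cfg$pbl_wind_cor >= 1) {
    stop("pbl_wind_cor must lie in (0, 1)", call. = FALSE)
  }
  if (length(cfg$temp_mortality_effects) != 10L) {
    stop("temp_mortality_effects must have length 10 (one per decile)",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_days, "days, seed", x$seed, "\n")
  cat("  theta (log RR per ug/m3):", signif(x$theta, 4),
      " confounding gamma =", x$gamma_confound,
      " kappa =", x$kappa_confound, "\n")
  cat("  baseline deaths:", x$deaths_baseline,
      " overdispersion:", x$overdispersion, "\n")
  invisible(x)
}
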