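# Instrument validity checks: Granger-style forward-exposure test for
# omitted confounding, and the exclusion-restriction test conditioning on
# observed pollution.

new_falsification_report <- function(test, fields) {
  structure(c(list(test = test), fields), class = "falsification_report")
}

#' Granger-style forward-exposure falsification test
#'
#' One joint quasi-Poisson fit of daily deaths on the backward instrument
#' exposure (mean of lags 0 and 1) *and* the forward exposure (mean of the
#' instrument on the second and third days after death — one day is skipped
#' between the two windows because of serial correlation in pollution),
#' plus the usual strata. An omitted confounder with broad temporal
#' structure would be associated with the instrument after death as well as
#' before; a nonzero forward coefficient therefore signals confounding,
#' while a null forward coefficient alongside an unchanged backward
#' coefficient supports the instrument. Both coefficients are reported as
#' percent change per IQR of the backward exposure.
#'
#' @param deaths Daily death counts.
#' @param instrument Calibrated per-day instrument series (numeric or
#'   `instrument_fit`).
#' @param strata [assign_strata()] result.
#' @param alpha Two-sided level for the confounding verdict.
#' @return A `falsification_report` with backward/forward coefficients,
#'   CIs, p-values and `confounding_detected`.
#' @export
granger_test <- function(deaths, instrument, strata, alpha = 0.05) {
  z <- if (inherits(instrument, "instrument_fit")) instrument$instrument
       else as.numeric(instrument)
  backward <- lag_mean(z, c(0L, 1L))
  forward <- lag_mean(z, c(-2L, -3L))
  qp <- quasi_poisson_fit(deaths,
                          data.frame(backward = backward, forward = forward),
                          strata)
  iqr_b <- iqr(backward[!is.na(backward) & !is.na(forward)])
  back <- coef_per_iqr(qp$fit, "backward", iqr_b)
  fwd <- coef_per_iqr(qp$fit, "forward", iqr_b)
  new_falsification_report("granger", list(
    backward_percent = back$percent, backward_ci = back$ci,
    backward_p = back$p, backward_b = back$b,
    forward_percent = fwd$percent, forward_ci = fwd$ci,
    forward_p = fwd$p, forward_b = fwd$b,
    iqr = iqr_b, alpha = alpha,
    confounding_detected = !is.na(fwd$p) && fwd$p < alpha,
    n_days = qp$n_used, n_dropped = qp$n_dropped,
    model = qp$fit
  ))
}

#' Exclusion-restriction test: instrument conditional on pollution
#'
#' If the instrument affects mortality only through pollution (the
#' exclusion restriction), then conditioning on the observed pollutant
#' should absorb the association: in a joint quasi-Poisson fit of deaths on
#' the instrument exposure and the pollutant exposure (both lag-0,1 means)
#' plus strata, the instrument coefficient should be indistinguishable from
#' zero. A significant residual instrument association signals another
#' path from meteorology to mortality.
#'
#' @param deaths Daily death counts.
#' @param instrument Calibrated per-day instrument (numeric or
#'   `instrument_fit`).
#' @param pollutant Observed pollutant concentration series.
#' @param strata [assign_strata()] result.
#' @param alpha Two-sided level for the verdict.
#' @return A `falsification_report` with both conditional coefficients,
#'   p-values and `exclusion_violated`.
#' @export
exclusion_test <- function(deaths, instrument, pollutant, strata,
                           alpha = 0.05) {
  z <- if (inherits(instrument, "instrument_fit")) instrument$instrument
       else as.numeric(instrument)
  z_exp <- lag_mean(z, c(0L, 1L))
  a_exp <- lag_mean(as.numeric(pollutant), c(0L, 1L))
  rho <- suppressWarnings(cor(z_exp, a_exp, use = "complete.obs"))
  if (is.finite(rho) && abs(rho) > 0.99) {
    warning("instrument and pollutant exposures are nearly collinear ",
            sprintf("(|r| = %.3f); test is uninformative", abs(rho)),
            call. = FALSE)
  }
  qp <- quasi_poisson_fit(deaths,
                          data.frame(instrument = z_exp, pollutant = a_exp),
                          strata)
  iqr_z <- iqr(z_exp[!is.na(z_exp) & !is.na(a_exp)])
  iqr_a <- iqr(a_exp[!is.na(z_exp) & !is.na(a_exp)])
  zc <- coef_per_iqr(qp$fit, "instrument", iqr_z)
  ac <- coef_per_iqr(qp$fit, "pollutant", iqr_a)
  new_falsification_report("exclusion", list(
    instrument_percent = zc$percent, instrument_ci = zc$ci,
    instrument_p = zc$p, instrument_b = zc$b,
    pollutant_percent = ac$percent, pollutant_ci = ac$ci,
    pollutant_p = ac$p, pollutant_b = ac$b,
    exposure_cor = rho, alpha = alpha,
    exclusion_violated = !is.na(zc$p) && zc$p < alpha,
    n_days = qp$n_used, n_dropped = qp$n_dropped,
    model = qp$fit
  ))
}

#' @export
print.falsification_report <- function(x, ...) {
  if (x$test == "granger") {
    cat("<falsification_report> Granger forward-exposure test\n")
    cat(sprintf("  backward (lags 0,1): %.2f%% per IQR (95%% CI %.2f, %.2f)\n",
                x$backward_percent, x$backward_ci[1], x$backward_ci[2]))
    cat(sprintf("  forward (leads 2,3): %.2f%% per IQR (95%% CI %.2f, %.2f), p = %.3f\n",
                x$forward_percent, x$forward_ci[1], x$forward_ci[2],
                x$forward_p))
    cat("  confounding detected at alpha =", x$alpha, ":",
        x$confounding_detected, "\n")
  } else {
    cat("<falsification_report> exclusion-restriction test\n")
    cat(sprintf("  instrument | pollutant: %.2f%% per IQR, p = %.3f\n",
                x$instrument_percent, x$instrument_p))
    cat(sprintf("  pollutant  | instrument: %.2f%% per IQR, p = %.3f\n",
                x$pollutant_percent, x$pollutant_p))
    cat("  exclusion violated at alpha =", x$alpha, ":",
        x$exclusion_violated, "\n")
  }
  invisible(x)
}
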