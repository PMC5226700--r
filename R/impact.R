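# Health-impact translation of the rate ratio into attributable deaths.

#' Attributable deaths from a percent-per-IQR effect
#'
#' Converts an estimated percent increase in daily deaths per IQR of
#' exposure into the number of deaths over the study period attributable to
#' that exposure increment, using the attributable fraction among the
#' exposed applied to all deaths:
#' `RR = 1 + percent/100`, `AF = (RR - 1) / RR`,
#' `attributable = total_deaths * AF`.
#'
#' @param total_deaths Total deaths during follow-up (> 0).
#' @param percent_per_iqr Percent change in daily deaths per IQR (> -100).
#' @return An `impact_estimate` object: `total_deaths`, `rr_per_iqr`,
#'   `attributable_fraction`, `attributable_deaths`.
#' @export
#' @examples
#' attributable_deaths(204386, 0.90) # ~1823 deaths
attributable_deaths <- function(total_deaths, percent_per_iqr) {
  if (!is.finite(total_deaths) || total_deaths <= 0) {
    stop("total_deaths must be a positive count", call. = FALSE)
  }
  if (!is.finite(percent_per_iqr) || percent_per_iqr <= -100) {
    stop("percent_per_iqr must exceed -100", call. = FALSE)
  }
  rr <- 1 + percent_per_iqr / 100
  af <- (rr - 1) / rr
  structure(list(
    total_deaths = total_deaths,
    rr_per_iqr = rr,
    attributable_fraction = af,
    attributable_deaths = total_deaths * af
  ), class = "impact_estimate")
}

#' @export
print.impact_estimate <- function(x, ...) {
  cat("<impact_estimate>\n")
  cat(sprintf("  RR per IQR = %.5f, attributable fraction = %.5f\n",
              x$rr_per_iqr, x$attributable_fraction))
  cat(sprintf("  attributable deaths = %.1f of %d total\n",
              x$attributable_deaths, round(x$total_deaths)))
  invisible(x)
}
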