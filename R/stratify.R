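# Month-by-year and temperature-decile stratification, and removal of
# additive stratum effects from exposure series.

#' Assign month-by-year and temperature-decile strata
#'
#' Each day is labelled with its calendar month-of-year (`"2003-07"`) and
#' with the decile of its temperature relative to the full study period.
#' Decile cutpoints are the 0.1, ..., 0.9 quantiles (linear interpolation,
#' type 7); day t falls in decile k when its temperature lies in
#' (q\[k-1\], q\[k\]\], so ties at a cutpoint go to the lower decile. With
#' distinct temperatures the deciles are balanced to within rounding.
#'
#' @param panel A data.frame with at least `date` (Date) and `temperature`
#'   columns, dates strictly increasing.
#' @return A `stratum_assignment` data.frame with columns `date`,
#'   `month_year` (factor) and `temp_decile` (integer 1-10), and attribute
#'   `cutpoints` (the 9 quantiles).
#' @export
#' @examples
#' p <- data.frame(date = seq(as.Date("2000-01-01"), by = "day",
#'                            length.out = 740),
#'                 temperature = rnorm(740))
#' s <- assign_strata(p)
#' table(s$temp_decile)
assign_strata <- function(panel) {
  stopifnot(is.data.frame(panel), nrow(panel) > 0,
            all(c("date", "temperature") %in% names(panel)))
  temp <- panel$temperature
  if (all(!is.finite(temp))) {
    stop("all temperatures missing or non-finite; cannot form deciles",
         call. = FALSE)
  }
  if (any(diff(as.numeric(panel$date)) <= 0)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if (any(diff(as.numeric(panel$date)) > 1)) {
    warning("date gaps present in panel", call. = FALSE)
  }
  month_year <- factor(format(panel$date, "%Y-%m"))
  small <- table(month_year) < 5
  if (any(small)) {
    warning("month-year strata with < 5 days: ",
            paste(names(which(small)), collapse = ", "), call. = FALSE)
  }
  q <- quantile(temp, probs = seq(0.1, 0.9, by = 0.1), na.rm = TRUE,
                type = 7, names = FALSE)
  if (anyDuplicated(q)) {
    warning("tied temperature quantiles; fewer than 10 distinct deciles",
            call. = FALSE)
  }
  # (q[k-1], q[k]] intervals: ties at a cutpoint fall in the lower decile
  dec <- findInterval(temp, unique(q), left.open = TRUE) + 1L
  out <- data.frame(date = panel$date, month_year = month_year,
                    temp_decile = dec)
  attr(out, "cutpoints") <- q
  class(out) <- c("stratum_assignment", "data.frame")
  out
}

#' Remove additive month-by-year and temperature-decile effects
#'
#' Least-squares fit of the series on month-by-year indicators plus
#' temperature-decile indicators (one joint additive fit), returning the
#' residuals — the within-stratum variation of the series. The residual
#' mean is zero overall and within every level of each stratum factor.
#' Days with missing values are dropped from the fit and returned as `NA`;
#' the count is recorded in attribute `n_dropped`.
#'
#' @param series Numeric per-day series aligned with `strata`.
#' @param strata A [assign_strata()] result.
#' @return Numeric residual series (class `residual_series`), same length as
#'   `series`, with attribute `n_dropped`.
#' @export
orthogonalize <- function(series, strata) {
  stopifnot(inherits(strata, "stratum_assignment"),
            length(series) == nrow(strata))
  ok <- is.finite(series)
  if (!any(ok)) stop("no finite values to orthogonalize", call. = FALSE)
  df <- droplevels(data.frame(y = series,
                              month_year = strata$month_year,
                              decile = factor(strata$temp_decile))[ok, ,
                                                                   drop = FALSE])
  rhs <- c("month_year", "decile")[c(nlevels(df$month_year) > 1,
                                     nlevels(df$decile) > 1)]
  out <- rep(NA_real_, length(series))
  if (length(rhs)) {
    fit <- lm(stats::reformulate(rhs, response = "y"), data = df)
    out[ok] <- residuals(fit)
  } else {
    out[ok] <- df$y - mean(df$y)
  }
  attr(out, "n_dropped") <- sum(!ok)
  class(out) <- "residual_series"
  out
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat("<stratum_assignment>", nrow(x), "days,",
      nlevels(x$month_year), "month-year strata,",
      length(unique(x$temp_decile)), "temperature deciles\n")
  invisible(x)
}
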