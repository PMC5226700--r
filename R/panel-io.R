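# Reading and writing the daily-panel CSV schema.

PANEL_COLUMNS <- c("date", "deaths", "pm25", "bc", "no2", "pbl",
                   "wind_speed", "temperature")

#' Read a daily panel CSV
#'
#' Expects the schema `date,deaths,pm25,bc,no2,pbl,wind_speed,temperature`
#' with ISO-8601 dates. Basic sanity checks: strictly increasing dates,
#' nonnegative integer deaths, positive PBL, nonnegative wind speed.
#'
#' @param path CSV file path.
#' @param required Columns that must be present (default: `date` and
#'   `deaths`; pollutant columns are checked at analysis time).
#' @return Daily panel data.frame.
#' @export
read_panel <- function(path, required = c("date", "deaths")) {
  panel <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel$date <- as.Date(panel$date)
  if (anyNA(panel$date)) stop("unparseable dates in panel", call. = FALSE)
  if (any(diff(as.numeric(panel$date)) <= 0)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  if ("deaths" %in% names(panel)) {
    d <- panel$deaths
    if (any(is.finite(d) & (d < 0 | d != round(d)))) {
      stop("deaths must be nonnegative integers", call. = FALSE)
    }
  }
  if ("pbl" %in% names(panel) && any(panel$pbl <= 0, na.rm = TRUE)) {
    stop("pbl must be positive", call. = FALSE)
  }
  if ("wind_speed" %in% names(panel) &&
      any(panel$wind_speed < 0, na.rm = TRUE)) {
    stop("wind_speed must be nonnegative", call. = FALSE)
  }
  panel
}

#' Write a daily panel CSV
#'
#' @param panel Daily panel data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- panel
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the generator's truth sidecar
#'
#' Structured-text (DCF) summary of the simulation truth accompanying a
#' written panel: the true effect, confounding status and seed.
#'
#' @param truth `sim_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  df <- data.frame(
    theta_true = truth$theta_true,
    theta_per_iqr_true = truth$theta_per_iqr_true,
    oracle_iqr = truth$oracle_iqr,
    confounded = truth$confounded,
    gamma_confound = truth$config$gamma_confound,
    kappa_confound = truth$config$kappa_confound,
    seed = truth$seed
  )
  write.dcf(df, path)
  invisible(path)
}
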