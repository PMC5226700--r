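# First stage: calibrate the single pollution-calibrated instrument from
# PBL height and wind speed (lags 0 and 1) by radial-kernel support-vector
# regression, tuned by 10-fold cross-validated R-squared.

#' Interquartile range
#'
#' 75th minus 25th percentile with linear-interpolation quantiles (type 7),
#' over finite values only. The effect-reporting unit of the pipeline.
#'
#' @param x Numeric series with at least 4 finite values.
#' @return Scalar IQR.
#' @export
#' @examples
#' iqr(1:101) # 50
iqr <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("iqr needs at least 4 finite values",
                          call. = FALSE)
  unname(diff(quantile(x, c(0.25, 0.75), type = 7, names = FALSE)))
}

#' Instrument feature matrix: PBL and wind at lags 0 and 1
#'
#' The four instrumental variables of the first stage. The first panel day
#' has no lag-1 value and carries `NA`s.
#'
#' @param panel Data.frame with `pbl` and `wind_speed` columns.
#' @return Data.frame with columns `pbl_lag0, pbl_lag1, wind_lag0,
#'   wind_lag1`.
#' @export
instrument_features <- function(panel) {
  stopifnot(all(c("pbl", "wind_speed") %in% names(panel)))
  data.frame(
    pbl_lag0 = panel$pbl,
    pbl_lag1 = shift_series(panel$pbl, 1L),
    wind_lag0 = panel$wind_speed,
    wind_lag1 = shift_series(panel$wind_speed, 1L)
  )
}

#' Hyperparameter grid for the support-vector first stage
#'
#' Cost, radial-kernel width gamma (on standardized features) and epsilon
#' tube (on the standardized target). `svr_grid_reduced()` is a small grid
#' for Monte-Carlo work where full tuning per replicate is unnecessary.
#'
#' @param cost,gamma,epsilon Candidate values; all combinations are tried.
#' @return Data.frame of hyperparameter combinations.
#' @export
svr_grid <- function(cost = c(0.1, 1, 10, 100),
                     gamma = c(0.05, 0.25, 1, 4),
                     epsilon = 0.1) {
  expand.grid(cost = cost, gamma = gamma, epsilon = epsilon,
              KEEP.OUT.ATTRS = FALSE)
}

#' @rdname svr_grid
#' @export
svr_grid_reduced <- function() svr_grid(cost = 1, gamma = 0.25)

#' Fit the pollution-calibrated instrument
#'
#' Support-vector regression (radial kernel, ridge-type cost penalty) of the
#' stratum-residualized pollutant on the four instrument features, with
#' hyperparameters chosen to maximize out-of-fold R-squared over a seeded
#' k-fold partition, then refit on all data. R-squared is `1 - SSE/SST`
#' against the residualized target. Features are standardized to zero mean
#' and unit variance before kernel evaluation; the target is standardized
#' internally and predictions are returned on its original scale.
#'
#' By default the per-day instrument series consists of *out-of-fold*
#' (cross-fitted) predictions at the selected hyperparameters: each day's
#' value comes from the model fit with that day's fold held out. In-sample
#' predictions from the final refit (`prediction = "refit"`) partially
#' memorize the target noise — including any confounder-driven component of
#' pollution — and re-import into the second stage exactly the bias the
#' instrument exists to remove; cross-fitting keeps the instrument a
#' function of meteorology and *other* days only. The refit model is still
#' returned for prediction on new data and for the training R-squared.
#'
#' A best cross-validated R-squared at or below `weak_r2` aborts with a
#' `pbliv_weak_instrument` error: an instrument that barely predicts
#' exposure cannot support second-stage inference. A training R-squared
#' more than 0.05 below the CV R-squared is flagged as an overfit
#' diagnostic failure (`overfit_flag`).
#'
#' @param features [instrument_features()] output (or any 4-column numeric
#'   data.frame aligned to the panel).
#' @param target Stratum-residualized pollutant series ([orthogonalize()]).
#' @param folds Number of cross-validation folds (default 10).
#' @param grid Hyperparameter grid, see [svr_grid()].
#' @param seed Seed for the fold partition.
#' @param weak_r2 Weak-instrument threshold on the best CV R-squared.
#' @param block_folds Use contiguous time blocks instead of random days as
#'   folds (autocorrelation-robust check).
#' @param prediction `"crossfit"` (default): the instrument series is the
#'   out-of-fold predictions at the selected hyperparameters;
#'   `"refit"`: in-sample predictions of the final all-data refit.
#' @return An `instrument_fit` object: `model`, `hyperparameters`, per-day
#'   `instrument` (NA on days without features/target), `exposure` (its
#'   lag-0,1 mean), `cv_r2`, `train_r2`, `iqr` (of the exposure),
#'   `overfit_flag`, `n_fit`, `fold_seed`, `cv_table`.
#' @export
fit_instrument <- function(features, target, folds = 10L,
                           grid = svr_grid(), seed = 1L,
                           weak_r2 = 0.02, block_folds = FALSE,
                           prediction = c("crossfit", "refit")) {
  prediction <- match.arg(prediction)
  stopifnot(is.data.frame(features), nrow(grid) >= 1)
  target <- as.numeric(target)
  stopifnot(length(target) == nrow(features))
  keep <- complete.cases(features) & is.finite(target)
  n <- sum(keep)
  if (n < 200) {
    stop("fit_instrument needs at least 200 aligned days; got ", n,
         call. = FALSE)
  }
  X <- scale(as.matrix(features[keep, , drop = FALSE]))
  y_raw <- target[keep]
  y_c <- mean(y_raw); y_s <- sd(y_raw)
  if (y_s == 0) stop("target has zero variance", call. = FALSE)
  y <- (y_raw - y_c) / y_s

  set.seed(seed)
  fold_id <- if (block_folds) {
    as.integer(cut(seq_len(n), folds, labels = FALSE))
  } else {
    sample(rep_len(seq_len(folds), n))
  }

  sse_tot <- sum((y - mean(y))^2)
  cv_r2 <- numeric(nrow(grid))
  oof <- matrix(NA_real_, n, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr],
                      type = "eps-regression", kernel = "radial",
                      cost = grid$cost[g], gamma = grid$gamma[g],
                      epsilon = grid$epsilon[g], scale = FALSE)
      oof[!tr, g] <- predict(m, X[!tr, , drop = FALSE])
    }
    cv_r2[g] <- 1 - sum((y - oof[, g])^2) / sse_tot
  }
  best <- which.max(cv_r2)
  if (cv_r2[best] <= weak_r2) {
    cond <- structure(
      list(message = sprintf(
        paste0("weak instrument: best cross-validated R2 = %.4f <= %.2f; ",
               "the instrument is too weakly associated with exposure ",
               "for second-stage inference"), cv_r2[best], weak_r2),
        call = sys.call(-1), cv_r2 = cv_r2[best]),
      class = c("pbliv_weak_instrument", "error", "condition"))
    stop(cond)
  }

  final <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      epsilon = grid$epsilon[best], scale = FALSE)
  fitted_y <- predict(final, X)
  train_r2 <- 1 - sum((y - fitted_y)^2) / sse_tot

  instrument <- rep(NA_real_, nrow(features))
  instrument[keep] <- switch(prediction,
                             crossfit = oof[, best],
                             refit = fitted_y) * y_s + y_c
  exposure <- lag_mean(instrument, c(0L, 1L))
  structure(list(
    model = final,
    center = list(x_center = attr(X, "scaled:center"),
                  x_scale = attr(X, "scaled:scale"),
                  y_center = y_c, y_scale = y_s),
    hyperparameters = grid[best, , drop = FALSE],
    cv_table = cbind(grid, cv_r2 = cv_r2),
    cv_r2 = cv_r2[best],
    train_r2 = train_r2,
    overfit_flag = train_r2 < cv_r2[best] - 0.05,
    instrument = instrument,
    exposure = exposure,
    iqr = iqr(exposure),
    prediction = prediction,
    n_fit = n,
    folds = folds,
    fold_seed = seed
  ), class = "instrument_fit")
}

#' Lag-averaged instrument exposure
#'
#' The exposure series entering the mortality model: the mean of the
#' calibrated instrument on the day of death and the preceding day,
#' `(Z[t] + Z[t-1]) / 2`; undefined (NA) where either day is missing.
#'
#' @param fit An `instrument_fit` object (or a numeric instrument series).
#' @return Numeric per-day exposure series.
#' @export
instrument_exposure <- function(fit) {
  z <- if (inherits(fit, "instrument_fit")) fit$instrument else
    as.numeric(fit)
  lag_mean(z, c(0L, 1L))
}

#' @export
print.instrument_fit <- function(x, ...) {
  hp <- x$hyperparameters
  cat("<instrument_fit> radial-kernel SVR on", x$n_fit, "days\n")
  cat(sprintf("  cost = %g, gamma = %g, epsilon = %g (%d-fold CV)\n",
              hp$cost, hp$gamma, hp$epsilon, x$folds))
  cat(sprintf("  CV R2 = %.3f, training R2 = %.3f%s\n", x$cv_r2, x$train_r2,
              if (x$overfit_flag) "  [overfit flag]" else ""))
  cat(sprintf("  IQR of lag-averaged instrument = %.3f\n", x$iqr))
  invisible(x)
}
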