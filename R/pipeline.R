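# End-to-end orchestration: simulate/load -> stratify -> fit instrument ->
# second stage -> subset analysis -> falsification -> impact.

#' Pipeline run configuration
#'
#' @param panel Path to a panel CSV, or a panel data.frame; `NULL` to
#'   simulate via `sim`.
#' @param sim A [sim_config()] used when `panel` is `NULL`.
#' @param pollutant Which pollutant the instrument is calibrated to
#'   (`"pm25"`, `"bc"` or `"no2"`).
#' @param folds Cross-validation folds for the first stage.
#' @param grid First-stage hyperparameter grid ([svr_grid()]).
#' @param subset_max Concentration threshold of the low-concentration
#'   sensitivity analysis (`NA` to skip).
#' @param alpha Level for the falsification verdicts.
#' @param seed Top-level seed; the simulation and first-stage fold
#'   partition both derive their streams from it.
#' @param outdir Output directory (created if needed); `NULL` for none.
#' @return A `run_config` list.
#' @export
run_config <- function(panel = NULL, sim = NULL, pollutant = "pm25",
                       folds = 10L, grid = svr_grid(), subset_max = 30,
                       alpha = 0.05, seed = 1L, outdir = NULL) {
  pollutant <- match.arg(pollutant, c("pm25", "bc", "no2"))
  if (is.null(panel) && is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(panel = panel, sim = sim, pollutant = pollutant,
                 folds = as.integer(folds), grid = grid,
                 subset_max = subset_max, alpha = alpha,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the full instrumental-variable pipeline
#'
#' Executes, in order: panel load/simulation, stratum assignment,
#' orthogonalization of the chosen pollutant, first-stage instrument
#' calibration, second-stage IV estimate, naive (observed-pollutant)
#' estimate for comparison, low-concentration subset estimate, Granger and
#' exclusion falsification tests, and the attributable-death computation
#' (with the panel's own total deaths). When `outdir` is set, writes the
#' strata, instrument series, estimates and a run manifest there.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list with all stage outputs and the
#'   manifest; invisibly writes files when `outdir` is configured.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  panel <- stage("load", {
    if (is.null(config$panel)) {
      sim <- generate_panel(config$sim)
      truth <- sim$truth
      sim$panel
    } else if (is.character(config$panel)) {
      read_panel(config$panel)
    } else {
      config$panel
    }
  })
  if (!config$pollutant %in% names(panel)) {
    stop("pipeline stage 'load' failed: panel is missing pollutant column '",
         config$pollutant, "'", call. = FALSE)
  }

  strata <- stage("stratify", assign_strata(panel))
  resid <- stage("orthogonalize",
                 orthogonalize(panel[[config$pollutant]], strata))
  feats <- stage("features", instrument_features(panel))
  inst <- stage("fit-instrument",
                fit_instrument(feats, resid, folds = config$folds,
                               grid = config$grid, seed = config$seed))
  exposure <- instrument_exposure(inst)
  iv <- stage("fit", fit_iv_model(panel$deaths, exposure, strata,
                                  iqr_value = inst$iqr))
  naive <- stage("fit-naive",
                 fit_iv_model(panel$deaths,
                              lag_mean(panel[[config$pollutant]], c(0L, 1L)),
                              strata))
  subset_iv <- NULL
  if (is.finite(config$subset_max)) {
    subset_iv <- stage("subset", {
      keep <- is.na(panel[[config$pollutant]]) |
        panel[[config$pollutant]] <= config$subset_max
      # second-stage exclusion only: instrument and strata from full period
      fit_iv_model(ifelse(keep, panel$deaths, NA_integer_), exposure,
                   strata, iqr_value = inst$iqr)
    })
  }
  granger <- stage("falsify-granger",
                   granger_test(panel$deaths, inst, strata,
                                alpha = config$alpha))
  exclusion <- stage("falsify-exclusion",
                     exclusion_test(panel$deaths, inst,
                                    panel[[config$pollutant]], strata,
                                    alpha = config$alpha))
  impact <- stage("impact",
                  attributable_deaths(sum(panel$deaths),
                                      iv$percent_per_iqr))

  manifest <- list(
    pollutant = config$pollutant,
    seed = config$seed,
    n_days_panel = nrow(panel),
    n_days_analysis = iv$n_days,
    simulated = is.null(config$panel),
    first_stage = list(hyperparameters = as.list(inst$hyperparameters),
                       cv_r2 = inst$cv_r2, train_r2 = inst$train_r2,
                       iqr = inst$iqr),
    iv_percent_per_iqr = iv$percent_per_iqr,
    iv_ci95 = iv$ci95_percent,
    naive_percent_per_iqr = naive$percent_per_iqr,
    subset_percent_per_iqr = if (!is.null(subset_iv))
      subset_iv$percent_per_iqr else NA_real_,
    granger_forward_percent = granger$forward_percent,
    granger_forward_p = granger$forward_p,
    exclusion_instrument_p = exclusion$instrument_p,
    attributable_deaths = impact$attributable_deaths,
    true_percent_per_iqr = if (!is.null(truth))
      truth$theta_per_iqr_true else NA_real_,
    r_version = as.character(getRversion())
  )

  result <- structure(list(
    panel = panel, truth = truth, strata = strata, residual = resid,
    instrument = inst, iv = iv, naive = naive, subset = subset_iv,
    granger = granger, exclusion = exclusion, impact = impact,
    manifest = manifest, config = config
  ), class = "pipeline_result")

  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_panel(result$panel, fp("panel.csv"))
  if (!is.null(result$truth)) write_sim_truth(result$truth, fp("truth.dcf"))
  strata_df <- data.frame(date = format(result$strata$date, "%Y-%m-%d"),
                          month_year = result$strata$month_year,
                          temp_decile = result$strata$temp_decile)
  write.csv(strata_df, fp("strata.csv"), row.names = FALSE, quote = FALSE)
  inst_df <- data.frame(date = format(result$panel$date, "%Y-%m-%d"),
                        instrument = result$instrument$instrument,
                        exposure_lagmean = result$instrument$exposure)
  write.csv(inst_df, fp("instrument.csv"), row.names = FALSE, quote = FALSE)
  est_row <- function(label, est) {
    data.frame(pollutant = result$config$pollutant, analysis = label,
               percent_per_iqr = est$percent_per_iqr,
               ci_low = est$ci95_percent[1], ci_high = est$ci95_percent[2],
               dispersion = est$dispersion, n_days = est$n_days,
               iqr = est$iqr)
  }
  ests <- rbind(est_row("iv", result$iv), est_row("naive", result$naive))
  if (!is.null(result$subset)) {
    ests <- rbind(ests, est_row("iv_low_concentration", result$subset))
  }
  write.csv(ests, fp("estimates.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> pollutant:", x$config$pollutant, "\n")
  cat(sprintf("  first stage: CV R2 = %.3f (training %.3f), IQR = %.3f\n",
              x$instrument$cv_r2, x$instrument$train_r2, x$instrument$iqr))
  cat(sprintf("  IV:    %.2f%% per IQR (95%% CI %.2f, %.2f)\n",
              x$iv$percent_per_iqr, x$iv$ci95_percent[1],
              x$iv$ci95_percent[2]))
  cat(sprintf("  naive: %.2f%% per IQR\n", x$naive$percent_per_iqr))
  if (!is.null(x$subset)) {
    cat(sprintf("  low-concentration subset: %.2f%% per IQR\n",
                x$subset$percent_per_iqr))
  }
  cat(sprintf("  Granger forward: %.2f%% (p = %.2f); exclusion p = %.2f\n",
              x$granger$forward_percent, x$granger$forward_p,
              x$exclusion$instrument_p))
  cat(sprintf("  attributable deaths: %.1f\n",
              x$impact$attributable_deaths))
  invisible(x)
}
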