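# Forecast accuracy metrics, reported on physical scales after inverse
# normalization.

#' Mean absolute error
#' @param y_pred,y_obs Equal-length numeric vectors (or arrays).
#' @return A scalar.
#' @export
mae <- function(y_pred, y_obs) {
  check_metric_input(y_pred, y_obs)
  mean(abs(y_pred - y_obs))
}

#' Root mean squared error
#' @inheritParams mae
#' @return A scalar; always >= the MAE of the same pair.
#' @export
rmse <- function(y_pred, y_obs) {
  check_metric_input(y_pred, y_obs)
  sqrt(mean((y_pred - y_obs)^2))
}

check_metric_input <- function(y_pred, y_obs) {
  if (length(y_pred) == 0 || length(y_obs) == 0) abort("empty input to a metric")
  if (length(y_pred) != length(y_obs)) abort("prediction and observation lengths differ")
  invisible(NULL)
}

#' Coefficient of determination, two dialects
#'
#' `form = "standard"` is the usual `1 - SSE/SST`. `form = "printed"`
#' is the explained-variance ratio `sum((y_pred - mean(y_obs))^2) /
#' sum((y_obs - mean(y_obs))^2)`, which some forecasting papers print
#' as R-squared; it equals the standard form for an unbiased linear fit
#' but can exceed 1 in general. Standard is the default reporting form.
#'
#' @inheritParams mae
#' @param form `"standard"` or `"printed"`.
#' @return A scalar.
#' @export
r_squared <- function(y_pred, y_obs, form = c("standard", "printed")) {
  form <- match.arg(form)
  check_metric_input(y_pred, y_obs)
  if (length(y_obs) < 2) abort("R-squared needs at least 2 observations")
  ybar <- mean(y_obs)
  sst <- sum((y_obs - ybar)^2)
  if (sst == 0) abort("R-squared is undefined for constant observations")
  if (form == "printed") {
    sum((y_pred - ybar)^2) / sst
  } else {
    1 - sum((y_obs - y_pred)^2) / sst
  }
}

#' Per-target accuracy report on physical scales
#'
#' Computes MAE, RMSE and R-squared per target channel from
#' denormalized prediction and observation arrays. Guards against the
#' classic mistake of scoring on the normalized scale: temperature,
#' humidity and CO2 readings from a rabbit house never all live in the
#' unit interval, so an all-in-[0, 1] observation array raises.
#'
#' @param y_pred,y_obs `S x H x 3` arrays on physical scales (targets
#'   ordered Tin, RHin, CO2).
#' @param r2_form Passed to [r_squared()].
#' @return A tibble with columns `target, unit, mae, rmse, r2, n`.
#' @export
metrics_report <- function(y_pred, y_obs, r2_form = "standard") {
  stopifnot(length(dim(y_pred)) == 3, all(dim(y_pred) == dim(y_obs)))
  if (all(y_obs >= -0.05 & y_obs <= 1.05)) {
    abort(paste0("observations all lie in [0, 1]: they look normalized; ",
                 "denormalize before computing metrics"))
  }
  units <- rhp_channel_units()
  purrr::map_dfr(seq_len(dim(y_obs)[3]), function(i) {
    ch <- rhp_env_channels()[i]
    p <- as.numeric(y_pred[, , i]); o <- as.numeric(y_obs[, , i])
    tibble(target = ch, unit = units[[ch]],
           mae = mae(p, o), rmse = rmse(p, o),
           r2 = r_squared(p, o, r2_form), n = length(o))
  })
}

#' Improvement of a proposed error over a baseline error, in percent
#'
#' `form = "decrease"` reports `100 * (baseline - proposed) / baseline`
#' rounded half-up to one decimal (the convention for "RMSE decreased
#' by 39.1%"); `form = "increase"` reports
#' `100 * (proposed - baseline) / baseline` rounded to the nearest
#' integer (the convention for "RMSE increased by 122%" in ablation
#' summaries, where `baseline` is the full model).
#'
#' @param baseline Positive reference error.
#' @param proposed Comparison error.
#' @param form `"decrease"` or `"increase"`.
#' @return The rounded percentage.
#' @export
improvement_pct <- function(baseline, proposed, form = c("decrease", "increase")) {
  form <- match.arg(form)
  if (!is.numeric(baseline) || baseline <= 0) abort("`baseline` must be positive")
  if (form == "decrease") {
    round_half_up(100 * (baseline - proposed) / baseline, 1)
  } else {
    round_half_up(100 * (proposed - baseline) / baseline, 0)
  }
}
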