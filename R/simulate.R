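# Synthetic rabbit-house microclimate generator.
#
# Process family: sinusoidal diurnal mesor/amplitude for the outdoor
# drivers, AR(1) Gaussian noise for sensor/weather irregularity, a
# first-order lag filter for the indoor thermal response, linear
# cross-channel coupling on standardized deviations, and an
# occupancy/ventilation-driven CO2 diurnal cycle. The simplest process
# family that is simultaneously periodic, non-stationary, nonlinear in
# its couplings and strongly cross-correlated, which is what summer
# sensor records from enclosed rabbit houses look like.

ar1_noise <- function(n, sd, ar) {
  if (sd <= 0) return(rep(0, n))
  innov <- rnorm(n) * sd * sqrt(1 - ar^2)
  as.numeric(stats::filter(innov, ar, method = "recursive",
                           init = rnorm(1) * sd))
}

zdev <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

lag_filter <- function(x, tau_steps) {
  # y_t = y_{t-1} + (x_t - y_{t-1}) / tau  (discrete first-order response)
  a <- 1 / tau_steps
  as.numeric(stats::filter(a * x, 1 - a, method = "recursive", init = x[1]))
}

#' Simulate a multichannel rabbit-house sensor series
#'
#' Generates the six-channel series (indoor temperature, relative
#' humidity, CO2, air speed; outdoor temperature and humidity) for a
#' regional preset. Outdoor temperature follows a diurnal sinusoid whose
#' seven-day mean attains the preset's published max/min (exactly so when
#' noise is switched off); outdoor humidity is anti-phased with it;
#' indoor channels are lagged low-pass responses plus linear coupling
#' terms and an occupancy-driven CO2 cycle. Fully deterministic given the
#' config seed. No artifacts yet: see [inject_artifacts()].
#'
#' @param preset An [make_region_preset()] preset.
#' @param config An [sim_config()] object.
#' @return A tibble of class `rhp_series` with columns
#'   `timestamp, Tin, RHin, CO2, WS, Tout, RHout`.
#' @export
simulate_house <- function(preset, config) {
  stopifnot(inherits(preset, "rhp_preset"), inherits(config, "rhp_sim_config"))
  validate_preset(preset)
  set.seed(config$seed)

  step <- config$step_minutes
  n <- config$n_days * 24L * 60L %/% step
  t0 <- as.POSIXct("2023-08-20 00:00:00", tz = "UTC")
  ts <- t0 + seq(0, by = 60 * step, length.out = n)
  hour <- (as.numeric(ts - t0, units = "hours")) %% 24

  ar <- preset$ar_coefficient
  nsd <- preset$noise_sd
  # afternoon temperature peak at 15:00, trough 03:00
  phase <- sin(2 * pi * (hour - 9) / 24)

  t_mes <- (preset$outdoor_temp_max + preset$outdoor_temp_min) / 2
  t_amp <- (preset$outdoor_temp_max - preset$outdoor_temp_min) / 2
  tout <- t_mes + t_amp * phase + ar1_noise(n, nsd[["Tout"]], ar)

  rh_mes <- (preset$outdoor_rh_max + preset$outdoor_rh_min) / 2
  rh_amp <- (preset$outdoor_rh_max - preset$outdoor_rh_min) / 2
  rhout <- rh_mes - rh_amp * phase + ar1_noise(n, nsd[["RHout"]], ar)
  rhout <- pmin(100, pmax(0, rhout))

  ws <- preset$wind_mean * (1 + 0.3 * sin(2 * pi * (hour - 12) / 24)) +
    ar1_noise(n, nsd[["WS"]], ar)
  ws <- pmax(0, ws)

  C <- preset$coupling
  # indoor temperature: ~1.5 h thermal lag behind outdoors, plus offset
  tau_steps <- max(1, 90 / step)
  tin <- preset$indoor_offset_temp + lag_filter(tout, tau_steps) +
    C["Tin", "WS"] * zdev(ws) * 0.5 +
    ar1_noise(n, nsd[["Tin"]], ar)

  rhin <- preset$indoor_rh_level +
    C["RHin", "Tin"] * zdev(tin) * 6 +
    C["RHin", "RHout"] * zdev(rhout) * 6 +
    ar1_noise(n, nsd[["RHin"]], ar)
  rhin <- pmin(100, pmax(0, rhin))

  # ventilation is lowest (and stocked animals' exhalation accumulates)
  # in the small hours: CO2 peaks near 04:00
  co2 <- preset$co2_base +
    preset$co2_amplitude * cos(2 * pi * (hour - 4) / 24) +
    C["CO2", "Tin"] * zdev(tin) * 0.4 * preset$co2_amplitude +
    C["CO2", "WS"] * zdev(ws) * 0.4 * preset$co2_amplitude +
    ar1_noise(n, nsd[["CO2"]], ar)
  co2 <- pmax(50, co2)

  out <- tibble(timestamp = ts, Tin = tin, RHin = rhin, CO2 = co2,
                WS = ws, Tout = tout, RHout = rhout)
  out <- set_step_minutes(out, step)
  attr(out, "region") <- preset$name
  class(out) <- c("rhp_series", class(out))
  out
}

#' Pairwise Pearson correlations of a sensor table
#'
#' Pairwise-complete Pearson correlation over the six channels,
#' mirroring the correlation heatmaps used to describe cross-channel
#' coupling strength in barn microclimate data.
#'
#' @param table A sensor table (raw or cleaned); masked entries are
#'   excluded pairwise.
#' @return A symmetric 6x6 correlation matrix with unit diagonal.
#'   Entries involving a constant channel are `NA` with a warning, never
#'   silently zero.
#' @export
pearson_matrix <- function(table) {
  stopifnot_series(table)
  m <- as.matrix(table[, rhp_channels()])
  enough <- all(apply(!is.na(m), 2, sum) >= 3)
  if (!enough) abort("need at least 3 non-missing observations per channel")
  const <- apply(m, 2, function(x) sd(x, na.rm = TRUE) == 0)
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  if (any(const)) {
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
    diag(r)[!const] <- 1
    diag(r)[const] <- NA_real_
    warn(paste0("constant channel(s): ",
                paste(rhp_channels()[const], collapse = ", "),
                "; their correlations are undefined (NA)"))
  }
  r
}
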