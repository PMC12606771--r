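# Regional presets for the synthetic rabbit-house simulator.
#
# The outdoor temperature / humidity anchors are the published seven-day
# late-summer statistics for the three source regions; indoor levels,
# coupling strengths and noise scales are free simulator parameters chosen
# to respect the qualitative regional ordering (the south-eastern coastal
# site hottest, most humid and most strongly coupled; the north-western
# site coolest with the largest diurnal swings, high CO2 and the weakest
# coupling).

region_table <- function() {
  tibble::tribble(
    ~name,     ~outdoor_temp_max, ~outdoor_temp_min, ~outdoor_rh_max, ~outdoor_rh_min,
    "fujian",  30.15,             23.51,             98.09,           74.25,
    "gansu",   23.15,             15.73,             95.03,           59.93,
    "henan",   29.97,             20.45,             97.15,           67.26
  )
}

default_coupling <- function(name) {
  # coupling[i, j]: contribution of channel j's standardized deviation to
  # channel i, in units of channel i's own scale. Only the indoor channels
  # receive coupling terms; signs are fixed (warmer -> drier indoor air,
  # warmer / stiller -> more CO2), magnitudes vary by region.
  ch <- rhp_channels()
  m <- matrix(0, 6, 6, dimnames = list(ch, ch))
  strength <- switch(name, fujian = 1.0, henan = 0.7, gansu = 0.4)
  m["RHin", "Tin"] <- -0.55 * strength
  m["RHin", "RHout"] <- 0.45 * strength
  m["CO2", "Tin"] <- 0.45 * strength
  m["CO2", "WS"] <- -0.35 * strength
  m["Tin", "WS"] <- -0.15 * strength
  m
}

#' Build a regional simulator preset
#'
#' Returns the full parameter set the synthetic microclimate generator
#' needs for one of the three supported source regions. Outdoor
#' temperature and humidity bounds are the regions' seven-day mean
#' late-summer statistics; indoor levels and coupling coefficients are
#' simulator defaults (see the methods vignette).
#'
#' @param name One of `"fujian"`, `"gansu"`, `"henan"`.
#' @return An object of class `rhp_preset`: a list with outdoor bounds
#'   (degC, %RH), indoor level parameters, a 6x6 `coupling` matrix,
#'   per-channel `noise_sd`, and an AR(1) `ar_coefficient`.
#' @examples
#' make_region_preset("fujian")$outdoor_temp_max
#' @export
make_region_preset <- function(name) {
  tab <- region_table()
  if (!is.character(name) || length(name) != 1 || !name %in% tab$name) {
    abort(paste0("unknown region ", deparse(name), "; valid regions are: ",
                 paste(tab$name, collapse = ", ")))
  }
  row <- tab[tab$name == name, ]
  indoor <- switch(name,
    # offset of indoor over outdoor mean temperature; RH running level;
    # CO2 mesor/diurnal amplitude; mean air speed
    fujian = list(offset = 1.5, rh = 80, co2_base = 900, co2_amp = 250, ws = 1.2),
    gansu  = list(offset = 2.5, rh = 62, co2_base = 1400, co2_amp = 450, ws = 0.8),
    henan  = list(offset = 2.0, rh = 70, co2_base = 1100, co2_amp = 350, ws = 1.0)
  )
  noise_sd <- c(Tin = 0.18, RHin = 0.9, CO2 = 28, WS = 0.12,
                Tout = 0.35, RHout = 1.6)
  preset <- list(
    name = name,
    outdoor_temp_max = row$outdoor_temp_max,
    outdoor_temp_min = row$outdoor_temp_min,
    outdoor_rh_max = row$outdoor_rh_max,
    outdoor_rh_min = row$outdoor_rh_min,
    indoor_offset_temp = indoor$offset,
    indoor_rh_level = indoor$rh,
    co2_base = indoor$co2_base,
    co2_amplitude = indoor$co2_amp,
    wind_mean = indoor$ws,
    coupling = default_coupling(name),
    noise_sd = noise_sd,
    ar_coefficient = 0.97
  )
  class(preset) <- "rhp_preset"
  validate_preset(preset)
  preset
}

validate_preset <- function(p) {
  stopifnot(
    p$outdoor_temp_max > p$outdoor_temp_min,
    p$outdoor_rh_max > p$outdoor_rh_min,
    p$outdoor_rh_max <= 100, p$outdoor_rh_min >= 0,
    p$co2_base > 0,
    p$ar_coefficient >= 0, p$ar_coefficient < 1,
    all(p$noise_sd >= 0)
  )
  invisible(p)
}

#' @export
print.rhp_preset <- function(x, ...) {
  cat("<rhp_preset> region:", x$name, "\n")
  cat(sprintf("  outdoor T: %.2f-%.2f degC (range %.2f)\n",
              x$outdoor_temp_min, x$outdoor_temp_max,
              x$outdoor_temp_max - x$outdoor_temp_min))
  cat(sprintf("  outdoor RH: %.2f-%.2f %%RH (range %.2f)\n",
              x$outdoor_rh_min, x$outdoor_rh_max,
              x$outdoor_rh_max - x$outdoor_rh_min))
  cat(sprintf("  indoor: +%.1f degC offset, %.0f %%RH, CO2 %.0f+/-%.0f ppm\n",
              x$indoor_offset_temp, x$indoor_rh_level,
              x$co2_base, x$co2_amplitude))
  invisible(x)
}

#' Simulation settings for the synthetic generator
#'
#' @param n_days Number of simulated days (>= 1).
#' @param step_minutes Sampling interval in minutes; must divide 60.
#'   Default 1, the cadence of the real sensor network.
#' @param seed Integer seed; every stochastic draw in the generator is
#'   derived from it.
#' @param outlier_rate Fraction of table rows replaced by sensor spikes
#'   when artifacts are injected, in `[0, 0.05]`.
#' @param gap_spec List of `c(start_row, duration_minutes)` pairs marking
#'   spans of lost data.
#' @return An `rhp_sim_config` list.
#' @export
sim_config <- function(n_days = 14, step_minutes = 1, seed = 1,
                       outlier_rate = 0, gap_spec = list()) {
  stopifnot(n_days >= 1, step_minutes >= 1, 60 %% step_minutes == 0,
            outlier_rate >= 0, outlier_rate <= 0.05)
  structure(list(n_days = n_days, step_minutes = step_minutes,
                 seed = as.integer(seed), outlier_rate = outlier_rate,
                 gap_spec = gap_spec),
            class = "rhp_sim_config")
}
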