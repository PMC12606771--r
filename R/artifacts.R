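# Sensor artifact injection: isolated spikes (abnormally high/low
# readings) and missing spans (network/power loss), with a complete log
# so detector recall and masking arithmetic are testable.

robust_sd <- function(x) 1.4826 * median(abs(x - median(x, na.rm = TRUE)), na.rm = TRUE)

#' Inject sensor artifacts into a clean synthetic series
#'
#' Replaces a seeded random set of readings with spikes displaced at
#' least 6 robust standard deviations from the local level, and masks
#' the spans in `gap_spec` (all channels) as missing. The spike
#' magnitude is chosen to sit safely beyond a threshold-3 robust
#' detector, so detector recall is measurable. Every artifact is
#' recorded in the `artifact_log` attribute of the result.
#'
#' @param table A clean `rhp_series` table (no pre-existing `NA`s).
#' @param config An [sim_config()]; `outlier_rate` and `gap_spec` drive
#'   the injection, `seed` (offset) the placement.
#' @return The table with artifacts applied; `attr(, "artifact_log")` is
#'   a tibble with columns `row, channel, kind, original, value`.
#' @export
inject_artifacts <- function(table, config) {
  stopifnot_series(table)
  stopifnot(inherits(config, "rhp_sim_config"))
  if (anyNA(table[, rhp_channels()])) {
    abort("`table` already contains missing values; inject artifacts into a clean series.")
  }
  set.seed(config$seed + 104729L)  # independent stream from simulate_house
  n <- nrow(table)
  step <- series_step_minutes(table)
  out <- table
  log <- list()

  n_spikes <- floor(config$outlier_rate * n)
  if (n_spikes > 0) {
    cells <- sample.int(n * 6L, n_spikes)
    rows <- ((cells - 1L) %% n) + 1L
    chans <- rhp_channels()[((cells - 1L) %/% n) + 1L]
    for (i in seq_len(n_spikes)) {
      ch <- chans[i]; r <- rows[i]
      x <- out[[ch]]
      w <- max(1, r - 30):min(n, r + 30)
      level <- median(x[w])
      s <- robust_sd(x)
      if (s == 0) s <- max(abs(level), 1)
      mag <- s * runif(1, 6, 9) * sample(c(-1, 1), 1)
      log[[length(log) + 1]] <- tibble(
        row = r, channel = ch, kind = "spike",
        original = x[r], value = level + mag)
      out[[ch]][r] <- level + mag
    }
  }

  for (g in config$gap_spec) {
    start <- g[[1]]
    dur_min <- g[[2]]
    len <- dur_min / step
    if (len != round(len)) abort("gap duration must be a multiple of the sampling step")
    idx <- start:(start + len - 1)
    if (start < 1 || max(idx) > n) {
      abort(sprintf("gap (%d, %g min) overlaps the table bounds (n = %d rows)",
                    start, dur_min, n))
    }
    for (ch in rhp_channels()) {
      log[[length(log) + 1]] <- tibble(
        row = idx, channel = ch, kind = "gap",
        original = out[[ch]][idx], value = NA_real_)
      out[[ch]][idx] <- NA_real_
    }
  }

  attr(out, "artifact_log") <-
    if (length(log)) bind_rows(log) else
      tibble(row = integer(), channel = character(), kind = character(),
             original = double(), value = double())
  out <- set_step_minutes(out, step)
  out
}

#' Retrieve the artifact log of a series
#' @param table A table returned by [inject_artifacts()].
#' @return The artifact log tibble (empty if none).
#' @export
artifact_log <- function(table) {
  log <- attr(table, "artifact_log")
  if (is.null(log)) {
    log <- tibble(row = integer(), channel = character(), kind = character(),
                  original = double(), value = double())
  }
  log
}
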