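# Preprocessing chain: Hampel-style sliding-window outlier masking,
# bounded-gap linear interpolation with segment breaks, block-mean
# down-sampling and a chronological 6:1:3 split.

#' Mask outliers with a sliding-window robust filter
#'
#' Hampel-style detector: for each point, the robust z-score
#' `|x - running median| / (1.4826 * running MAD)` is computed over a
#' centered window; points exceeding `z_threshold` are set to missing
#' (masked), all others are left untouched.
#'
#' @param table A sensor table.
#' @param window Odd window length in samples (>= 5). Default 61: one
#'   hour plus the center point at minute resolution, wide enough to be
#'   robust against the diurnal trend.
#' @param z_threshold Robust z cutoff, default 3.
#' @return The table with flagged points masked (`NA`); the mask
#'   positions are in `attr(, "outlier_mask")` as a tibble
#'   `(row, channel, value, z)`.
#' @export
detect_outliers <- function(table, window = 61, z_threshold = 3) {
  stopifnot_series(table)
  if (window < 5 || window %% 2 == 0) abort("`window` must be odd and >= 5")
  if (z_threshold <= 0) abort("`z_threshold` must be positive")
  if (window > nrow(table)) abort("`window` is longer than the series")

  out <- table
  flagged <- list()
  for (ch in rhp_channels()) {
    x <- table[[ch]]
    obs <- !is.na(x)
    if (sum(obs) < window) next
    # runmed needs a complete series; bridge masked points by linear
    # interpolation for the reference level only
    xf <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
    med <- stats::runmed(xf, window, endrule = "median")
    dev <- abs(xf - med)
    # floor the running scale at 1% of the channel's global robust SD so
    # that near-noiseless smooth stretches (running MAD ~ 0) do not
    # produce spurious detections from curvature alone
    floor_scale <- 0.01 * robust_sd(xf)
    scale <- pmax(1.4826 * stats::runmed(dev, window, endrule = "median"),
                  floor_scale)
    z <- ifelse(dev == 0, 0, dev / scale)  # 0/0 (flat window) -> clean
    bad <- obs & is.finite(x) & z > z_threshold
    if (any(bad)) {
      flagged[[ch]] <- tibble(row = which(bad), channel = ch,
                              value = x[bad], z = z[bad])
      out[[ch]][bad] <- NA_real_
    }
  }
  attr(out, "outlier_mask") <-
    if (length(flagged)) bind_rows(flagged) else
      tibble(row = integer(), channel = character(), value = double(), z = double())
  out <- set_step_minutes(out, series_step_minutes(table))
  attr(out, "artifact_log") <- attr(table, "artifact_log")
  out
}

fill_channel <- function(x, max_run) {
  # linear interpolation y_k = y1 + k/(n+1) * (y2 - y1) for interior runs
  # of length <= max_run; longer runs and edge runs stay missing
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]; n_run <- r$lengths[i]
    if (s == 1 || e == length(x) || n_run > max_run) next
    y1 <- x[s - 1]; y2 <- x[e + 1]
    k <- seq_len(n_run)
    x[s:e] <- y1 + k / (n_run + 1) * (y2 - y1)
  }
  x
}

#' Interpolate short gaps and break the series at long ones
#'
#' Missing runs no longer than `max_gap_minutes` (and not touching the
#' series ends) are filled by linear interpolation
#' `y_k = y1 + k/(n+1) * (y2 - y1)` between the nearest valid
#' neighbours. Longer runs cannot be imputed: the rows still missing in
#' any channel are dropped and the series is broken into continuity
#' segments across which no training window may span.
#'
#' @param table A sensor table (typically after [detect_outliers()]).
#' @param max_gap_minutes Longest imputable gap, default 60.
#' @return A cleaned tibble with an added integer `segment` column and
#'   no missing values. `attr(, "segment_breaks")` records the dropped
#'   row spans.
#' @export
fill_gaps <- function(table, max_gap_minutes = 60) {
  stopifnot_series(table)
  step <- series_step_minutes(table)
  if (is.na(step)) abort("cannot infer the sampling step from the table")
  max_run <- floor(max_gap_minutes / step)

  out <- table
  for (ch in rhp_channels()) out[[ch]] <- fill_channel(out[[ch]], max_run)

  complete <- stats::complete.cases(out[, rhp_channels()])
  seg <- cumsum(c(TRUE, diff(which(complete)) > 1))
  breaks <- tibble(row_start = integer(), row_end = integer())
  if (any(!complete)) {
    r <- rle(!complete)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    breaks <- tibble(row_start = starts[r$values], row_end = ends[r$values])
  }
  clean <- out[complete, ]
  clean$segment <- if (nrow(clean)) seg else integer()
  clean <- set_step_minutes(clean, step)
  attr(clean, "segment_breaks") <- breaks
  class(clean) <- unique(c("rhp_series", class(clean)))
  clean
}

#' Down-sample a cleaned series by block means
#'
#' Averages non-overlapping blocks of `factor` consecutive points within
#' each continuity segment (trailing remainders dropped), so a
#' minute-resolution series becomes a 10-minute series with
#' `factor = 10`. Block timestamps are the block-start times.
#'
#' @param table A cleaned table from [fill_gaps()].
#' @param factor Block length, default 10.
#' @return The down-sampled cleaned table; the sampling step attribute
#'   is multiplied by `factor`.
#' @export
downsample_mean <- function(table, factor = 10) {
  stopifnot_series(table, require_segments = TRUE)
  if (factor <= 0 || factor != round(factor)) abort("`factor` must be a positive integer")
  step <- series_step_minutes(table)
  if (factor == 1) return(table)
  pieces <- lapply(split(seq_len(nrow(table)), table$segment), function(idx) {
    n_blocks <- length(idx) %/% factor
    if (n_blocks == 0) return(NULL)
    keep <- idx[seq_len(n_blocks * factor)]
    block <- rep(seq_len(n_blocks), each = factor)
    vals <- lapply(rhp_channels(), function(ch) {
      as.numeric(tapply(table[[ch]][keep], block, mean))
    })
    names(vals) <- rhp_channels()
    tibble(timestamp = table$timestamp[keep][seq(1, by = factor, length.out = n_blocks)],
           !!!vals, segment = table$segment[idx[1]])
  })
  out <- bind_rows(pieces)
  out <- out[order(out$timestamp), ]
  out <- set_step_minutes(out, step * factor)
  class(out) <- unique(c("rhp_series", class(out)))
  out
}

#' Sizes of a chronological train/validation/test split
#'
#' Train and validation sizes are rounded half-up from the exact ratio
#' shares; the test set takes the remainder, so the three sizes always
#' sum to `m`. With the default 6:1:3 ratio, `m = 7548` gives
#' (4529, 755, 2264).
#'
#' @param m Number of rows to split (>= 10).
#' @param ratios Length-3 positive weights, default `c(6, 1, 3)`.
#' @return Named integer vector `(train, val, test)`.
#' @export
split_sizes <- function(m, ratios = c(6, 1, 3)) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  if (m < 10) abort("need at least 10 rows to split")
  w <- ratios / sum(ratios)
  n_train <- as.integer(round_half_up(w[1] * m))
  n_val <- as.integer(round_half_up(w[2] * m))
  c(train = n_train, val = n_val, test = as.integer(m) - n_train - n_val)
}

#' Split a series chronologically into train/validation/test
#'
#' Contiguous, ordered thirds (no shuffling, no leakage): the earliest
#' rows train, the middle validate, the latest test. Accepts either a
#' cleaned table or a plain row count (in which case only the sizes are
#' returned).
#'
#' @param table A cleaned table, or a single integer row count.
#' @param ratios Length-3 positive weights, default `c(6, 1, 3)`.
#' @return A named list `(train, val, test)` of tables, or the
#'   [split_sizes()] vector when `table` is a count.
#' @export
chronological_split <- function(table, ratios = c(6, 1, 3)) {
  if (is.numeric(table) && length(table) == 1) {
    return(split_sizes(table, ratios))
  }
  stopifnot_series(table)
  sizes <- split_sizes(nrow(table), ratios)
  step <- series_step_minutes(table)
  idx <- list(train = seq_len(sizes[["train"]]),
              val = sizes[["train"]] + seq_len(sizes[["val"]]),
              test = sizes[["train"]] + sizes[["val"]] + seq_len(sizes[["test"]]))
  lapply(idx, function(i) set_step_minutes(table[i, ], step))
}
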