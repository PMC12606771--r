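# Reversible per-channel min-max scaling:
#   x_scaled = (x - xmin) / (xmax - xmin + 1e-7)
# The 1e-7 guard makes the constant-channel case well defined (all
# zeros) and is part of the transform, so it is also inverted exactly.

NORM_EPS <- 1e-7

#' Fit a min-max normalization state
#'
#' Computes per-channel minima and maxima from the supplied table. Fit
#' this on the training portion only, then reuse the state for the
#' validation/test portions and at inference, so no information leaks
#' backwards from the future.
#'
#' @param train_portion A cleaned sensor table (training rows).
#' @return An `rhp_norm_state` tibble with columns
#'   `channel, xmin, xmax` and the fixed epsilon as an attribute.
#' @export
fit_normalizer <- function(train_portion) {
  stopifnot_series(train_portion)
  if (nrow(train_portion) == 0) abort("cannot fit a normalizer on an empty table")
  state <- purrr::map_dfr(rhp_channels(), function(ch) {
    x <- train_portion[[ch]]
    tibble(channel = ch, xmin = min(x, na.rm = TRUE), xmax = max(x, na.rm = TRUE))
  })
  attr(state, "epsilon") <- NORM_EPS
  class(state) <- c("rhp_norm_state", class(state))
  state
}

check_norm_state <- function(table, state) {
  if (!inherits(state, "rhp_norm_state")) abort("`state` must come from fit_normalizer()")
  if (!setequal(state$channel, rhp_channels())) {
    abort("normalization state channels do not match the table channels")
  }
  invisible(state)
}

#' Apply / invert min-max normalization
#'
#' `normalize()` maps each channel through
#' `(x - xmin) / (xmax - xmin + 1e-7)`; `denormalize()` inverts it. The
#' round trip is exact to well below 1e-9 relative error, including for
#' constant channels (which normalize to all zeros).
#'
#' @param table A sensor table.
#' @param state An `rhp_norm_state` from [fit_normalizer()].
#' @return The transformed table (same shape and attributes).
#' @export
normalize <- function(table, state) {
  stopifnot_series(table)
  check_norm_state(table, state)
  out <- table
  for (i in seq_len(nrow(state))) {
    ch <- state$channel[i]
    out[[ch]] <- (table[[ch]] - state$xmin[i]) / (state$xmax[i] - state$xmin[i] + NORM_EPS)
  }
  attr(out, "normalized") <- TRUE
  out
}

#' @rdname normalize
#' @export
denormalize <- function(table, state) {
  stopifnot_series(table)
  check_norm_state(table, state)
  out <- table
  for (i in seq_len(nrow(state))) {
    ch <- state$channel[i]
    out[[ch]] <- table[[ch]] * (state$xmax[i] - state$xmin[i] + NORM_EPS) + state$xmin[i]
  }
  attr(out, "normalized") <- NULL
  out
}

# denormalize an S x H x n_targets prediction/target array whose third
# dimension is ordered as `channels`
denorm_array <- function(a, state, channels = rhp_env_channels()) {
  for (j in seq_along(channels)) {
    i <- match(channels[j], state$channel)
    a[, , j] <- a[, , j] * (state$xmax[i] - state$xmin[i] + NORM_EPS) + state$xmin[i]
  }
  a
}

#' Write / read a normalization state as key-value JSON text
#' @param state An `rhp_norm_state`.
#' @param path File path.
#' @return `read_norm_state()` returns the state; `write_norm_state()`
#'   its path, invisibly.
#' @export
write_norm_state <- function(state, path) {
  if (!inherits(state, "rhp_norm_state")) abort("`state` must come from fit_normalizer()")
  payload <- list(epsilon = NORM_EPS,
                  channels = purrr::pmap(state, function(channel, xmin, xmax) {
                    list(channel = channel, xmin = xmin, xmax = xmax)
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_state
#' @export
read_norm_state <- function(path) {
  payload <- jsonlite::read_json(path)
  state <- purrr::map_dfr(payload$channels, ~ tibble(
    channel = .x$channel, xmin = as.numeric(.x$xmin), xmax = as.numeric(.x$xmax)))
  attr(state, "epsilon") <- NORM_EPS
  class(state) <- c("rhp_norm_state", class(state))
  state
}
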