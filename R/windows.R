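# Sliding-window sample construction. Windows are stride-1 and never
# cross a continuity segment break; targets are the three indoor
# channels over the horizon immediately following the input window.

#' Build model windows from a normalized, cleaned series
#'
#' Every stride-1 window of `N` input steps followed by `H` target steps
#' that fits wholly inside one continuity segment becomes one sample.
#' Inputs carry all six channels, targets only the three indoor ones
#' (temperature, humidity, CO2).
#'
#' @param table A cleaned (and usually normalized) table with a
#'   `segment` column.
#' @param n_input Input window length N in steps.
#' @param horizon Forecast horizon H in steps.
#' @return An `rhp_windows` object: list with `inputs` (S x N x 6),
#'   `targets` (S x H x 3), an `index` tibble mapping samples back to
#'   source rows, and `n_input`/`horizon`.
#' @export
make_windows <- function(table, n_input, horizon) {
  stopifnot_series(table, require_segments = TRUE)
  stopifnot(n_input >= 1, horizon >= 1)
  need <- n_input + horizon
  seg_len <- table(table$segment)
  if (!any(seg_len >= need)) {
    abort(sprintf("no continuity segment is long enough for N + H = %d steps", need))
  }

  env <- rhp_env_channels()
  mat <- as.matrix(table[, rhp_channels()])
  starts <- integer(); segs <- integer()
  for (s in unique(table$segment)) {
    rows <- which(table$segment == s)
    len <- length(rows)
    if (len < need) next
    st <- rows[seq_len(len - need + 1)]
    starts <- c(starts, st)
    segs <- c(segs, rep(s, length(st)))
  }
  n_samp <- length(starts)
  inputs <- array(0, dim = c(n_samp, n_input, 6),
                  dimnames = list(NULL, NULL, rhp_channels()))
  targets <- array(0, dim = c(n_samp, horizon, 3),
                   dimnames = list(NULL, NULL, env))
  for (i in seq_len(n_samp)) {
    r0 <- starts[i]
    inputs[i, , ] <- mat[r0:(r0 + n_input - 1), ]
    targets[i, , ] <- mat[(r0 + n_input):(r0 + need - 1), 1:3]
  }
  structure(list(inputs = inputs, targets = targets,
                 index = tibble(sample = seq_len(n_samp), segment = segs,
                                start_row = starts),
                 n_input = n_input, horizon = horizon,
                 normalized = isTRUE(attr(table, "normalized"))),
            class = "rhp_windows")
}

#' @export
print.rhp_windows <- function(x, ...) {
  cat(sprintf("<rhp_windows> %d samples, N = %d, H = %d%s\n",
              nrow(x$index), x$n_input, x$horizon,
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Number of samples in a window batch
#' @param w An `rhp_windows` object.
#' @return Integer sample count.
#' @export
n_windows <- function(w) dim(w$inputs)[1]

subset_windows <- function(w, idx) {
  structure(list(inputs = w$inputs[idx, , , drop = FALSE],
                 targets = w$targets[idx, , , drop = FALSE],
                 index = w$index[idx, ], n_input = w$n_input,
                 horizon = w$horizon, normalized = w$normalized),
            class = "rhp_windows")
}

concat_windows <- function(a, b) {
  stopifnot(a$n_input == b$n_input, a$horizon == b$horizon)
  ni <- dim(a$inputs)[1] + dim(b$inputs)[1]
  inputs <- array(0, dim = c(ni, a$n_input, 6))
  targets <- array(0, dim = c(ni, a$horizon, 3))
  inputs[seq_len(dim(a$inputs)[1]), , ] <- a$inputs
  inputs[dim(a$inputs)[1] + seq_len(dim(b$inputs)[1]), , ] <- b$inputs
  targets[seq_len(dim(a$targets)[1]), , ] <- a$targets
  targets[dim(a$targets)[1] + seq_len(dim(b$targets)[1]), , ] <- b$targets
  structure(list(inputs = inputs, targets = targets,
                 index = bind_rows(a$index, b$index),
                 n_input = a$n_input, horizon = a$horizon,
                 normalized = a$normalized && b$normalized),
            class = "rhp_windows")
}
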