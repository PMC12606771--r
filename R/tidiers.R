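# broom-style tidiers for fitted forecasters.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted forecaster: one row per parameter tensor
#'
#' @param x An `rhp_model` or `rhp_baseline`.
#' @param ... Unused.
#' @return A tibble with `parameter, rows, cols, n, mean, sd`.
#' @export
tidy.rhp_model <- function(x, ...) {
  purrr::imap_dfr(x$params, function(m, nm) {
    tibble(parameter = nm, rows = nrow(m), cols = ncol(m), n = length(m),
           mean = mean(m), sd = stats::sd(as.numeric(m)))
  })
}

#' @export
tidy.rhp_baseline <- tidy.rhp_model

#' One-row model summary
#'
#' @param x An `rhp_model` or `rhp_baseline`.
#' @param ... Unused.
#' @return A one-row tibble: architecture fields, parameter count,
#'   training state and (if trained) best-epoch losses.
#' @export
glance.rhp_model <- function(x, ...) {
  cfg <- x$config
  out <- tibble(n_input = cfg$n_input, horizon = cfg$horizon,
                patch_len = cfg$patch_len_eff, d = cfg$d,
                n_layers = cfg$n_layers, n_heads = cfg$n_heads,
                n_parameters = n_parameters(x), trained = isTRUE(x$trained),
                epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
                best_epoch = x$best_epoch %||% NA_integer_,
                best_val_loss = NA_real_, final_train_loss = NA_real_)
  if (!is.null(x$history) && nrow(x$history) > 0) {
    out$best_val_loss <- min(x$history$val_loss)
    out$final_train_loss <- x$history$train_loss[nrow(x$history)]
  }
  out
}

#' @export
glance.rhp_baseline <- function(x, ...) {
  out <- glance.rhp_model(x, ...)
  out$patch_len <- NA_integer_
  out$kind <- x$kind
  out
}
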