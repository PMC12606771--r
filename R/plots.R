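# ggplot2 visualisations for each result type.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   facet_grid labs theme_minimal vars scale_x_datetime
#' @export
ggplot2::autoplot

#' Plot a sensor series, one facet per channel
#'
#' @param object An `rhp_series` table.
#' @param channels Channels to show (default all six).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhp_series <- function(object, channels = rhp_channels(), ...) {
  units <- rhp_channel_units()
  long <- object %>%
    select("timestamp", dplyr::all_of(channels)) %>%
    tidyr::pivot_longer(-"timestamp", names_to = "channel", values_to = "value") %>%
    mutate(channel = factor(paste0(.data$channel, " [", units[.data$channel], "]"),
                            levels = paste0(channels, " [", units[channels], "]")))
  ggplot(long, aes(x = .data$timestamp, y = .data$value)) +
    geom_line(linewidth = 0.3, na.rm = TRUE) +
    facet_wrap(vars(.data$channel), scales = "free_y", ncol = 1) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot training history (train/validation loss per epoch)
#'
#' @param model A trained model with a `history` tibble.
#' @return A ggplot object.
#' @export
plot_training <- function(model) {
  if (is.null(model$history) || nrow(model$history) == 0) {
    abort("model has no training history")
  }
  long <- tidyr::pivot_longer(model$history, -"epoch",
                              names_to = "set", values_to = "loss")
  ggplot(long, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "epoch", y = "MSE loss (normalized scale)", colour = NULL) +
    theme_minimal()
}

#' Plot a length-sweep result table
#'
#' RMSE (or another metric) against input length, one line per horizon,
#' facetted by target.
#'
#' @param sweep A [length_sweep()] result.
#' @param metric One of `"rmse"`, `"mae"`, `"r2"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = "rmse") {
  stopifnot(metric %in% c("rmse", "mae", "r2"))
  ggplot(dplyr::filter(sweep, .data$status == "ok"),
         aes(x = .data$n_input, y = .data[[metric]],
             colour = factor(.data$horizon))) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(vars(.data$target), scales = "free_y") +
    labs(x = "input length N", y = metric, colour = "horizon H") +
    theme_minimal()
}

#' Plot transfer-protocol curves
#'
#' Metric against fine-tuning subset index (0 = zero-shot), one line
#' per initialization, facetted by target.
#'
#' @param transfer A [transfer_protocol()] result.
#' @param metric One of `"rmse"`, `"mae"`, `"r2"`.
#' @return A ggplot object.
#' @export
plot_transfer <- function(transfer, metric = "rmse") {
  stopifnot(metric %in% c("rmse", "mae", "r2"))
  ggplot(transfer, aes(x = .data$subset, y = .data[[metric]],
                       colour = .data$init)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(vars(.data$target), scales = "free_y") +
    labs(x = "fine-tuning subset (0 = zero-shot)", y = metric,
         colour = "initialization") +
    theme_minimal()
}

#' Plot forecasts against observations for one window
#'
#' @param pred `S x H x 3` forecast array (physical scale).
#' @param obs `S x H x 3` observation array (physical scale).
#' @param sample Window index to show.
#' @return A ggplot object.
#' @export
plot_forecast <- function(pred, obs, sample = 1) {
  H <- dim(pred)[2]
  long <- purrr::map_dfr(seq_len(dim(pred)[3]), function(i) {
    tibble(step = rep(seq_len(H), 2),
           target = rhp_env_channels()[i],
           series = rep(c("forecast", "observed"), each = H),
           value = c(pred[sample, , i], obs[sample, , i]))
  })
  ggplot(long, aes(x = .data$step, y = .data$value, colour = .data$series)) +
    geom_line() +
    facet_wrap(vars(.data$target), scales = "free_y") +
    labs(x = "horizon step", y = NULL, colour = NULL) +
    theme_minimal()
}
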