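# Recurrent baselines: stacked RNN / GRU / LSTM over the six input
# channels per time step, tanh activations, linear head to the H x 3
# forecast. Defaults mirror the comparison setting: three recurrent
# layers of 256 hidden units.

#' Build a recurrent baseline model
#'
#' @param kind One of `"rnn"`, `"gru"`, `"lstm"`.
#' @param config An [rhp_config()] (supplies N, H and the seed).
#' @param hidden Hidden units per layer, default 256.
#' @param n_rec_layers Stacked recurrent layers, default 3.
#' @return An `rhp_baseline` with the same forward contract as the main
#'   model (`predict()` returns `S x H x 3`).
#' @export
build_baseline <- function(kind, config, hidden = 256, n_rec_layers = 3) {
  kinds <- c("rnn", "gru", "lstm")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    abort(paste0("unknown baseline kind ", deparse(kind),
                 "; valid kinds: ", paste(kinds, collapse = ", ")))
  }
  stopifnot(inherits(config, "rhp_config"))
  set.seed(config$seed)
  n_in <- 6L
  gates <- switch(kind, rnn = 1L, gru = 3L, lstm = 4L)
  P <- list()
  for (l in seq_len(n_rec_layers)) {
    d_in <- if (l == 1) n_in else hidden
    for (g in seq_len(gates)) {
      P[[sprintf("l%d_W%d", l, g)]] <- uinit(d_in + hidden, hidden, d_in + hidden)
      P[[sprintf("l%d_b%d", l, g)]] <- matrix(0, 1, hidden)
    }
  }
  P$head_W <- uinit(hidden, config$horizon * 3L, hidden)
  P$head_b <- matrix(0, 1, config$horizon * 3L)
  structure(list(kind = kind, config = config, hidden = as.integer(hidden),
                 n_rec_layers = as.integer(n_rec_layers), params = P,
                 trained = FALSE, history = NULL),
            class = "rhp_baseline")
}

#' @export
print.rhp_baseline <- function(x, ...) {
  cat(sprintf("<rhp_baseline> %s: %d x %d hidden, N=%d H=%d, %d parameters\n",
              toupper(x$kind), x$n_rec_layers, x$hidden,
              x$config$n_input, x$config$horizon, n_parameters(x)))
  invisible(x)
}

baseline_forward_tape <- function(tape, Pn, inputs, model) {
  cfg <- model$config
  B <- dim(inputs)[1]; N <- dim(inputs)[2]
  hid <- model$hidden
  layer_in <- lapply(seq_len(N), function(t) ad_const(tape, matrix(inputs[, t, ], B, 6)))
  for (l in seq_len(model$n_rec_layers)) {
    W <- function(g) Pn[[sprintf("l%d_W%d", l, g)]]
    bb <- function(g) Pn[[sprintf("l%d_b%d", l, g)]]
    h <- ad_const(tape, matrix(0, B, hid))
    cc <- ad_const(tape, matrix(0, B, hid))  # lstm cell state
    outs <- vector("list", N)
    for (t in seq_len(N)) {
      x_t <- layer_in[[t]]
      hp <- ad_concat_cols(tape, list(h, x_t))
      lin <- function(g) ad_add_bias(tape, ad_matmul(tape, hp, W(g)), bb(g))
      if (model$kind == "rnn") {
        h <- ad_tanh(tape, lin(1))
      } else if (model$kind == "gru") {
        z <- ad_sigmoid(tape, lin(1))
        r <- ad_sigmoid(tape, lin(2))
        rh <- ad_mul(tape, r, h)
        cand <- ad_tanh(tape, ad_add_bias(tape,
                 ad_matmul(tape, ad_concat_cols(tape, list(rh, x_t)), W(3)), bb(3)))
        h <- ad_add(tape, ad_mul(tape, ad_one_minus(tape, z), h),
                    ad_mul(tape, z, cand))
      } else {
        i_g <- ad_sigmoid(tape, lin(1))
        f_g <- ad_sigmoid(tape, lin(2))
        o_g <- ad_sigmoid(tape, lin(3))
        g_g <- ad_tanh(tape, lin(4))
        cc <- ad_add(tape, ad_mul(tape, f_g, cc), ad_mul(tape, i_g, g_g))
        h <- ad_mul(tape, o_g, ad_tanh(tape, cc))
      }
      outs[[t]] <- h
    }
    layer_in <- outs
  }
  flat <- ad_add_bias(tape, ad_matmul(tape, layer_in[[N]], Pn$head_W), Pn$head_b)
  # split the H*3 head into per-target B x H blocks (targets interleaved last)
  lapply(seq_len(3), function(i) {
    ad_cols(tape, flat, (i - 1) * cfg$horizon + seq_len(cfg$horizon))
  })
}

#' @export
predict.rhp_baseline <- function(object, windows, batch_size = 256, ...) {
  check_window_shapes(object$config, windows)
  S <- n_windows(windows)
  pred <- array(0, dim = c(S, object$config$horizon, 3),
                dimnames = list(NULL, NULL, rhp_env_channels()))
  for (chunk in split(seq_len(S), ceiling(seq_len(S) / batch_size))) {
    tape <- ad_tape_new()
    Pn <- params_to_nodes(tape, object$params)
    outs <- baseline_forward_tape(tape, Pn,
                                  windows$inputs[chunk, , , drop = FALSE], object)
    for (i in seq_len(3)) pred[chunk, , i] <- outs[[i]]$value
  }
  pred
}

#' Persistence (naive) forecaster
#'
#' Repeats the last observed value of each target channel across the
#' whole horizon — the standard naive reference any trained forecaster
#' must beat.
#'
#' @param windows An `rhp_windows` batch.
#' @return An `S x H x 3` array of persistence forecasts.
#' @export
persistence_forecast <- function(windows) {
  S <- n_windows(windows)
  H <- windows$horizon
  pred <- array(0, dim = c(S, H, 3), dimnames = list(NULL, NULL, rhp_env_channels()))
  last <- windows$inputs[, windows$n_input, 1:3, drop = FALSE]
  for (h in seq_len(H)) pred[, h, ] <- last[, 1, ]
  pred
}
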