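# The patch/cross-attention forecaster: configuration, seeded parameter
# initialization, and the tape-based forward pass used for training and
# prediction. The numeric primitives in layers.R define the semantics;
# the tape forward re-expresses them batched over samples.

#' Model configuration
#'
#' @param n_input Input sequence length N (in down-sampled steps).
#' @param horizon Forecast horizon H.
#' @param patch_len Patch length L; must divide N. When N < L the patch
#'   length falls back to N (single patch). Default 12 (two hours of
#'   10-minute steps).
#' @param d Feature (embedding) dimension, even. Default 256.
#' @param n_layers Number of encoder layers. Default 3.
#' @param n_heads Attention heads; `d` must be divisible. Default 1.
#' @param ffn_hidden Feed-forward hidden width. Default 512.
#' @param use_patch_encoding,use_aggregator,use_cross_attention Ablation
#'   switches for the three core modules (all `TRUE` for the full model).
#' @param n_aux Number of auxiliary channels (default 3).
#' @param seed Integer seed for weight initialization.
#' @return An `rhp_config` list.
#' @export
rhp_config <- function(n_input = 48, horizon = 12, patch_len = 12,
                       d = 256, n_layers = 3, n_heads = 1, ffn_hidden = 512,
                       use_patch_encoding = TRUE, use_aggregator = TRUE,
                       use_cross_attention = TRUE, n_aux = 3, seed = 1) {
  stopifnot(n_input >= 1, horizon >= 1, d >= 2, d %% 2 == 0,
            d %% n_heads == 0, n_layers >= 1, ffn_hidden >= 1, n_aux >= 1)
  l_eff <- effective_patch_len(n_input, patch_len)
  cfg <- list(n_input = as.integer(n_input), horizon = as.integer(horizon),
              patch_len = as.integer(patch_len), patch_len_eff = as.integer(l_eff),
              d = as.integer(d), n_layers = as.integer(n_layers),
              n_heads = as.integer(n_heads), ffn_hidden = as.integer(ffn_hidden),
              n_env = 3L, n_aux = as.integer(n_aux),
              use_patch_encoding = isTRUE(use_patch_encoding),
              use_aggregator = isTRUE(use_aggregator),
              use_cross_attention = isTRUE(use_cross_attention),
              seed = as.integer(seed))
  cfg$k <- as.integer(n_input %/% l_eff)
  # token count per environmental channel: k patches + 1 global token,
  # or the global token alone when patch encoding is ablated
  cfg$n_tokens <- if (cfg$use_patch_encoding) cfg$k + 1L else 1L
  class(cfg) <- "rhp_config"
  cfg
}

#' Desk-scale ("smoke") model configuration
#'
#' The reduced profile used by the test suite and worked examples:
#' d = 32, one encoder layer, feed-forward width 64.
#' @param ... Overrides passed to [rhp_config()].
#' @export
rhp_config_smoke <- function(...) {
  args <- modifyList(list(d = 32, n_layers = 1, ffn_hidden = 64), list(...))
  do.call(rhp_config, args)
}

uinit <- function(nr, nc, fan_in) {
  matrix(runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

init_params <- function(cfg) {
  set.seed(cfg$seed)
  d <- cfg$d; N <- cfg$n_input; L <- cfg$patch_len_eff
  P <- list()
  if (cfg$use_patch_encoding) {
    P$patch_W <- uinit(L, d, L); P$patch_b <- matrix(0, 1, d)
  }
  P$glob_W <- uinit(N, d, N); P$glob_b <- matrix(0, 1, d)
  if (cfg$use_cross_attention) {
    for (a in seq_len(cfg$n_aux)) {
      P[[paste0("aux_W", a)]] <- uinit(N, d, N)
      P[[paste0("aux_b", a)]] <- matrix(0, 1, d)
    }
  }
  for (l in seq_len(cfg$n_layers)) {
    pf <- function(nm) paste0("l", l, "_", nm)
    if (cfg$use_aggregator) P[[pf("agg_w")]] <- uinit(2 * d, 1, 2 * d)
    P[[pf("gru_Wz")]] <- uinit(2 * d, d, 2 * d)
    P[[pf("gru_Wr")]] <- uinit(2 * d, d, 2 * d)
    P[[pf("gru_W")]] <- uinit(2 * d, d, 2 * d)
    P[[pf("gru_bz")]] <- matrix(0, 1, d)
    P[[pf("gru_br")]] <- matrix(0, 1, d)
    P[[pf("gru_b")]] <- matrix(0, 1, d)
    if (cfg$use_cross_attention) {
      for (nm in c("att_Wq", "att_Wk", "att_Wv", "att_Wo")) P[[pf(nm)]] <- uinit(d, d, d)
      for (nm in c("att_bq", "att_bk", "att_bv", "att_bo")) P[[pf(nm)]] <- matrix(0, 1, d)
    }
    P[[pf("ln1_g")]] <- matrix(1, 1, d); P[[pf("ln1_b")]] <- matrix(0, 1, d)
    P[[pf("ffn_W1")]] <- uinit(d, cfg$ffn_hidden, d)
    P[[pf("ffn_b1")]] <- matrix(0, 1, cfg$ffn_hidden)
    P[[pf("ffn_W2")]] <- uinit(cfg$ffn_hidden, d, cfg$ffn_hidden)
    P[[pf("ffn_b2")]] <- matrix(0, 1, d)
    P[[pf("ln2_g")]] <- matrix(1, 1, d); P[[pf("ln2_b")]] <- matrix(0, 1, d)
  }
  for (i in seq_len(cfg$n_env)) {
    P[[paste0("head_W", i)]] <- uinit(cfg$n_tokens * d, cfg$horizon, cfg$n_tokens * d)
    P[[paste0("head_b", i)]] <- matrix(0, 1, cfg$horizon)
  }
  P
}

#' Build the patch/cross-attention forecaster
#'
#' Initializes a model with seeded uniform fan-in weights.
#'
#' @param config An [rhp_config()].
#' @return An `rhp_model` object (config + named parameter list).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "rhp_config"))
  structure(list(config = config, params = init_params(config),
                 trained = FALSE, history = NULL),
            class = "rhp_model")
}

#' Number of trainable parameters
#' @param model An `rhp_model` or `rhp_baseline`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.rhp_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<rhp_model> N=%d H=%d L=%d d=%d layers=%d heads=%d (%s)\n",
              cfg$n_input, cfg$horizon, cfg$patch_len_eff, cfg$d,
              cfg$n_layers, cfg$n_heads,
              if (x$trained) "trained" else "untrained"))
  flags <- c(patch = cfg$use_patch_encoding, aggregator = cfg$use_aggregator,
             cross_attention = cfg$use_cross_attention)
  cat("  modules:", paste(names(flags)[flags], collapse = ", "), "\n")
  cat("  parameters:", n_parameters(x), "\n")
  invisible(x)
}

## ---- tape forward -------------------------------------------------------

pe_row <- function(pos, d) matrix(positional_encoding(pos, d), 1)

# env: B x N x 3, aux: B x N x n_aux. Returns list of n_env nodes (B x H).
model_forward_tape <- function(tape, Pn, env, aux, cfg) {
  d <- cfg$d; N <- cfg$n_input; L <- cfg$patch_len_eff
  B <- dim(env)[1]
  kt <- cfg$n_tokens

  token_const <- function(mat, W, b, pos) {
    x <- ad_matmul(tape, ad_const(tape, mat), W)
    x <- ad_add_bias(tape, x, b)
    ad_add_bias(tape, x, ad_const(tape, pe_row(pos, d)))
  }

  # auxiliary channel tokens (keys/values), channel-index positional code
  aux_tokens <- NULL
  if (cfg$use_cross_attention) {
    aux_tokens <- lapply(seq_len(cfg$n_aux), function(a) {
      token_const(matrix(aux[, , a], B, N),
                  Pn[[paste0("aux_W", a)]], Pn[[paste0("aux_b", a)]], a)
    })
  }

  heads_out <- vector("list", cfg$n_env)
  for (c_i in seq_len(cfg$n_env)) {
    xc <- matrix(env[, , c_i], B, N)
    tokens <- list()
    if (cfg$use_patch_encoding) {
      for (j in seq_len(cfg$k)) {
        block <- xc[, ((j - 1) * L + 1):(j * L), drop = FALSE]
        tokens[[j]] <- token_const(block, Pn$patch_W, Pn$patch_b, j)
      }
    }
    tokens[[length(tokens) + 1]] <-
      token_const(xc, Pn$glob_W, Pn$glob_b, kt)

    for (l in seq_len(cfg$n_layers)) {
      pf <- function(nm) Pn[[paste0("l", l, "_", nm)]]
      # aggregator + GRU over the kt tokens
      h <- ad_const(tape, matrix(0, B, d))
      states <- vector("list", kt)
      for (t in seq_len(kt)) {
        if (cfg$use_aggregator) {
          scores <- lapply(tokens, function(p) {
            ad_tanh(tape, ad_matmul(tape, ad_concat_cols(tape, list(h, p)),
                                    pf("agg_w")))
          })
          alpha <- ad_softmax_rows(tape, ad_concat_cols(tape, scores))
          p_t <- NULL
          for (j in seq_along(tokens)) {
            term <- ad_mul_col(tape, tokens[[j]], ad_cols(tape, alpha, j))
            p_t <- if (is.null(p_t)) term else ad_add(tape, p_t, term)
          }
        } else {
          p_t <- tokens[[t]]
        }
        hp <- ad_concat_cols(tape, list(h, p_t))
        z <- ad_sigmoid(tape, ad_add_bias(tape, ad_matmul(tape, hp, pf("gru_Wz")),
                                          pf("gru_bz")))
        r <- ad_sigmoid(tape, ad_add_bias(tape, ad_matmul(tape, hp, pf("gru_Wr")),
                                          pf("gru_br")))
        rh <- ad_mul(tape, r, h)
        cand <- ad_tanh(tape, ad_add_bias(tape,
                 ad_matmul(tape, ad_concat_cols(tape, list(rh, p_t)), pf("gru_W")),
                 pf("gru_b")))
        h <- ad_add(tape, ad_mul(tape, ad_one_minus(tape, z), h),
                    ad_mul(tape, z, cand))
        states[[t]] <- h
      }

      # cross-attention with the auxiliary tokens, residual + layer norm
      new_tokens <- vector("list", kt)
      if (cfg$use_cross_attention) {
        dk <- d %/% cfg$n_heads
        keys <- lapply(aux_tokens, function(a) {
          ad_add_bias(tape, ad_matmul(tape, a, pf("att_Wk")), pf("att_bk"))
        })
        vals <- lapply(aux_tokens, function(a) {
          ad_add_bias(tape, ad_matmul(tape, a, pf("att_Wv")), pf("att_bv"))
        })
        for (t in seq_len(kt)) {
          q <- ad_add_bias(tape, ad_matmul(tape, states[[t]], pf("att_Wq")),
                           pf("att_bq"))
          head_parts <- vector("list", cfg$n_heads)
          for (hh in seq_len(cfg$n_heads)) {
            idx <- (hh - 1) * dk + seq_len(dk)
            qh <- ad_cols(tape, q, idx)
            sc <- lapply(seq_len(cfg$n_aux), function(a) {
              ad_scale(tape, ad_rowdot(tape, qh, ad_cols(tape, keys[[a]], idx)),
                       1 / sqrt(dk))
            })
            w <- ad_softmax_rows(tape, ad_concat_cols(tape, sc))
            part <- NULL
            for (a in seq_len(cfg$n_aux)) {
              term <- ad_mul_col(tape, ad_cols(tape, vals[[a]], idx),
                                 ad_cols(tape, w, a))
              part <- if (is.null(part)) term else ad_add(tape, part, term)
            }
            head_parts[[hh]] <- part
          }
          att <- ad_concat_cols(tape, head_parts)
          att <- ad_add_bias(tape, ad_matmul(tape, att, pf("att_Wo")), pf("att_bo"))
          new_tokens[[t]] <- ad_layernorm(tape, ad_add(tape, states[[t]], att),
                                          pf("ln1_g"), pf("ln1_b"))
        }
      } else {
        for (t in seq_len(kt)) {
          new_tokens[[t]] <- ad_layernorm(tape, states[[t]], pf("ln1_g"), pf("ln1_b"))
        }
      }

      # position-wise feed-forward, residual + layer norm
      for (t in seq_len(kt)) {
        x <- new_tokens[[t]]
        f <- ad_tanh(tape, ad_add_bias(tape, ad_matmul(tape, x, pf("ffn_W1")),
                                       pf("ffn_b1")))
        f <- ad_add_bias(tape, ad_matmul(tape, f, pf("ffn_W2")), pf("ffn_b2"))
        new_tokens[[t]] <- ad_layernorm(tape, ad_add(tape, x, f),
                                        pf("ln2_g"), pf("ln2_b"))
      }
      tokens <- new_tokens
    }

    flat <- ad_concat_cols(tape, tokens)
    heads_out[[c_i]] <- ad_add_bias(tape,
      ad_matmul(tape, flat, Pn[[paste0("head_W", c_i)]]),
      Pn[[paste0("head_b", c_i)]])
  }
  heads_out
}

params_to_nodes <- function(tape, P) {
  lapply(P, function(m) ad_const(tape, m))
}

forward_array <- function(model, env, aux) {
  tape <- ad_tape_new()
  Pn <- params_to_nodes(tape, model$params)
  outs <- model_forward_tape(tape, Pn, env, aux, model$config)
  pred <- array(0, dim = c(dim(env)[1], model$config$horizon, model$config$n_env),
                dimnames = list(NULL, NULL, rhp_env_channels()))
  for (i in seq_along(outs)) pred[, , i] <- outs[[i]]$value
  pred
}

#' Predict from a fitted (or freshly built) model
#'
#' @param object An `rhp_model`.
#' @param windows An `rhp_windows` batch whose inputs match the model's
#'   N; predictions are on the same (normalized) scale as the inputs.
#' @param batch_size Samples per forward pass.
#' @param ... Unused.
#' @return An `S x H x 3` array of forecasts.
#' @export
predict.rhp_model <- function(object, windows, batch_size = 256, ...) {
  check_window_shapes(object$config, windows)
  split_env_aux <- window_env_aux(windows)
  S <- n_windows(windows)
  pred <- array(0, dim = c(S, object$config$horizon, object$config$n_env),
                dimnames = list(NULL, NULL, rhp_env_channels()))
  for (chunk in split(seq_len(S), ceiling(seq_len(S) / batch_size))) {
    pred[chunk, , ] <- forward_array(object,
                                     split_env_aux$env[chunk, , , drop = FALSE],
                                     split_env_aux$aux[chunk, , , drop = FALSE])
  }
  pred
}

check_window_shapes <- function(cfg, windows) {
  if (!inherits(windows, "rhp_windows")) abort("`windows` must come from make_windows()")
  if (windows$n_input != cfg$n_input || windows$horizon != cfg$horizon) {
    abort(sprintf("window shape (N=%d, H=%d) does not match the model config (N=%d, H=%d)",
                  windows$n_input, windows$horizon, cfg$n_input, cfg$horizon))
  }
  invisible(windows)
}

window_env_aux <- function(windows) {
  list(env = windows$inputs[, , 1:3, drop = FALSE],
       aux = windows$inputs[, , 4:6, drop = FALSE])
}
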