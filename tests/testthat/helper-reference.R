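# Independent numeric reference for the network forward pass, composed
# step by step from the exported primitives (patchify, positional
# encoding, aggregate/GRU recurrence, cross-attention, plain layer-norm
# and feed-forward arithmetic). Used as the oracle the batched
# tape-based forward must match.

ref_layer_norm <- function(x, gain, bias, eps = 1e-5) {
  mu <- mean(x)
  xc <- x - mu
  xc / sqrt(mean(xc^2) + eps) * gain + bias
}

# one sample: env N x 3, aux N x n_aux; params/config from an rhp_model
reference_forward <- function(model, env, aux) {
  cfg <- model$config
  P <- model$params
  d <- cfg$d; N <- cfg$n_input; L <- cfg$patch_len_eff
  kt <- cfg$n_tokens

  embed <- function(x, W, b, pos) {
    as.numeric(x %*% W) + as.numeric(b) + positional_encoding(pos, d)
  }

  aux_tokens <- NULL
  if (cfg$use_cross_attention) {
    aux_tokens <- t(vapply(seq_len(cfg$n_aux), function(a) {
      embed(aux[, a], P[[paste0("aux_W", a)]], P[[paste0("aux_b", a)]], a)
    }, numeric(d)))
  }

  out <- matrix(0, cfg$horizon, cfg$n_env)
  for (c_i in seq_len(cfg$n_env)) {
    x <- env[, c_i]
    tokens <- NULL
    if (cfg$use_patch_encoding) {
      patches <- patchify(x, L)
      tokens <- t(vapply(seq_len(nrow(patches)), function(j) {
        embed(patches[j, ], P$patch_W, P$patch_b, j)
      }, numeric(d)))
    }
    tokens <- rbind(tokens, embed(x, P$glob_W, P$glob_b, kt))

    for (l in seq_len(cfg$n_layers)) {
      pf <- function(nm) P[[paste0("l", l, "_", nm)]]
      gru_params <- list(W_z = pf("gru_Wz"), W_r = pf("gru_Wr"), W = pf("gru_W"),
                         b_z = as.numeric(pf("gru_bz")),
                         b_r = as.numeric(pf("gru_br")),
                         b = as.numeric(pf("gru_b")))
      if (cfg$use_aggregator) gru_params$w_e <- as.numeric(pf("agg_w"))
      states <- encode_channel(tokens, gru_params,
                               use_aggregator = cfg$use_aggregator)

      if (cfg$use_cross_attention) {
        att_params <- list(W_q = pf("att_Wq"), W_k = pf("att_Wk"),
                           W_v = pf("att_Wv"), W_o = pf("att_Wo"),
                           b_q = as.numeric(pf("att_bq")), b_k = as.numeric(pf("att_bk")),
                           b_v = as.numeric(pf("att_bv")), b_o = as.numeric(pf("att_bo")),
                           ln_g = as.numeric(pf("ln1_g")), ln_b = as.numeric(pf("ln1_b")))
        tokens_new <- cross_attention(states, aux_tokens, att_params,
                                      n_heads = cfg$n_heads)
        attr(tokens_new, "weights") <- NULL
      } else {
        tokens_new <- t(apply(states, 1, ref_layer_norm,
                              gain = as.numeric(pf("ln1_g")),
                              bias = as.numeric(pf("ln1_b"))))
      }

      tokens <- t(vapply(seq_len(kt), function(t_i) {
        xt <- tokens_new[t_i, ]
        f <- tanh(as.numeric(xt %*% pf("ffn_W1")) + as.numeric(pf("ffn_b1")))
        f <- as.numeric(f %*% pf("ffn_W2")) + as.numeric(pf("ffn_b2"))
        ref_layer_norm(xt + f, as.numeric(pf("ln2_g")), as.numeric(pf("ln2_b")))
      }, numeric(d)))
    }

    flat <- as.numeric(t(tokens))
    # concatenation order must match the batched forward: token 1 cols,
    # token 2 cols, ... so flatten tokens row by row
    flat <- as.numeric(t(tokens))
    out[, c_i] <- as.numeric(flat %*% P[[paste0("head_W", c_i)]]) +
      as.numeric(P[[paste0("head_b", c_i)]])
  }
  out
}
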