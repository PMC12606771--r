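# Numeric reference implementations of the network's building blocks.
# These operate on plain vectors/matrices, are exported for direct use
# and testing, and define the exact semantics the trained network's
# tape-based forward pass must match.

#' Split a sequence into non-overlapping patches
#'
#' Divides a length-`N` series into `k = N / L` contiguous equal-length
#' patches. When the series is shorter than the requested patch length,
#' the patch length falls back to `N` (a single patch).
#'
#' @param x Numeric vector of length N.
#' @param patch_len Patch length L.
#' @return A `k x L` matrix whose rows are the ordered patches
#'   (so `as.numeric(t(patchify(x, L)))` restores `x`).
#' @export
patchify <- function(x, patch_len) {
  n <- length(x)
  l_eff <- if (n < patch_len) n else patch_len
  if (n %% l_eff != 0) {
    divs <- which(n %% seq_len(n) == 0)
    abort(sprintf("patch length %d does not divide the sequence length %d; valid lengths: %s",
                  patch_len, n, paste(divs, collapse = ", ")))
  }
  matrix(x, nrow = n %/% l_eff, ncol = l_eff, byrow = TRUE)
}

effective_patch_len <- function(n, patch_len) {
  l_eff <- if (n < patch_len) n else patch_len
  if (n %% l_eff != 0) {
    divs <- which(n %% seq_len(n) == 0)
    abort(sprintf("patch length %d does not divide the input length %d; valid lengths: %s",
                  patch_len, n, paste(divs, collapse = ", ")))
  }
  l_eff
}

#' Sinusoidal positional encoding
#'
#' Parameter-free encoding with
#' `p(pos, 2i) = sin(pos / 10000^(2i/d))` and
#' `p(pos, 2i+1) = cos(pos / 10000^(2i/d))` for dimension pairs
#' `i = 0, 1, ...` (zero-based, as is conventional).
#'
#' @param pos Non-negative step index (scalar).
#' @param d Even embedding dimension.
#' @return A length-`d` numeric vector with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(pos, d) {
  stopifnot(pos >= 0, d >= 2, d %% 2 == 0)
  i <- seq_len(d / 2) - 1
  angle <- pos / 10000^(2 * i / d)
  out <- numeric(d)
  out[2 * i + 1] <- sin(angle)
  out[2 * i + 2] <- cos(angle)
  out
}

#' One step of the patch-global aggregator
#'
#' Additive attention over the `k + 1` patch/global tokens, conditioned
#' on the recurrent hidden state: per-token scores
#' `e_j = tanh(w_e . [h_prev; p_j])` are softmax-normalized into
#' weights `alpha`, and the step input is the weighted token sum.
#'
#' @param tokens A `(k+1) x d` matrix of token vectors (rows).
#' @param h_prev Length-`d` hidden state from the previous step.
#' @param w_e Length-`2d` scoring vector.
#' @return List with `p_tilde` (length-`d` weighted combination) and
#'   `alpha` (the `k+1` softmax weights, non-negative, summing to 1).
#' @export
aggregate_step <- function(tokens, h_prev, w_e) {
  stopifnot(is.matrix(tokens), length(h_prev) == ncol(tokens),
            length(w_e) == 2 * ncol(tokens))
  e <- apply(tokens, 1, function(p) tanh(sum(w_e * c(h_prev, p))))
  e <- e - max(e)
  alpha <- exp(e) / sum(exp(e))
  list(p_tilde = as.numeric(colSums(alpha * tokens)), alpha = alpha)
}

#' One gated-recurrent-unit step
#'
#' Standard GRU update on the aggregated step input:
#' `z = sigmoid(W_z [h; p])`, `r = sigmoid(W_r [h; p])`,
#' `h_cand = tanh(W [r * h; p])`, `h' = (1 - z) * h + z * h_cand`.
#'
#' @param p_t Length-`d` step input.
#' @param h_prev Length-`d` previous hidden state.
#' @param params List with matrices `W_z`, `W_r`, `W` (each `2d x d`)
#'   and optional bias rows `b_z`, `b_r`, `b` (length `d`, default 0).
#' @return The new length-`d` hidden state.
#' @export
gru_cell <- function(p_t, h_prev, params) {
  d <- length(h_prev)
  b_z <- params$b_z %||% numeric(d)
  b_r <- params$b_r %||% numeric(d)
  b <- params$b %||% numeric(d)
  hp <- c(h_prev, p_t)
  z <- plogis(as.numeric(hp %*% params$W_z) + b_z)
  r <- plogis(as.numeric(hp %*% params$W_r) + b_r)
  h_cand <- tanh(as.numeric(c(r * h_prev, p_t) %*% params$W) + b)
  (1 - z) * h_prev + z * h_cand
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scaled dot-product cross-attention (numeric reference)
#'
#' Queries come from the temporally encoded environmental tokens,
#' keys/values from the channel-encoded auxiliary tokens:
#' `softmax(Q K' / sqrt(d_k)) V` per head, heads concatenated and
#' projected, added residually to the queries, then layer-normalized.
#'
#' @param queries `m x d` matrix.
#' @param keys_values `n x d` matrix.
#' @param params List with `W_q`, `W_k`, `W_v`, `W_o` (`d x d`),
#'   optional bias rows `b_q`, `b_k`, `b_v`, `b_o`, and layer-norm
#'   `ln_g`, `ln_b` (default 1 / 0).
#' @param n_heads Number of attention heads (`d` divisible by it).
#' @return `m x d` matrix; `attr(, "weights")` holds the `m x n`
#'   attention weights (averaged over heads), each row summing to 1.
#' @export
cross_attention <- function(queries, keys_values, params, n_heads = 1) {
  d <- ncol(queries)
  stopifnot(ncol(keys_values) == d, d %% n_heads == 0)
  add_bias <- function(m, b) if (is.null(b)) m else sweep(m, 2, b, "+")
  q <- add_bias(queries %*% params$W_q, params$b_q)
  k <- add_bias(keys_values %*% params$W_k, params$b_k)
  v <- add_bias(keys_values %*% params$W_v, params$b_v)
  dk <- d / n_heads
  heads <- vector("list", n_heads)
  wsum <- matrix(0, nrow(queries), nrow(keys_values))
  for (h in seq_len(n_heads)) {
    idx <- (h - 1) * dk + seq_len(dk)
    scores <- q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE]) / sqrt(dk)
    scores <- scores - apply(scores, 1, max)
    w <- exp(scores) / rowSums(exp(scores))
    wsum <- wsum + w
    heads[[h]] <- w %*% v[, idx, drop = FALSE]
  }
  att <- add_bias(do.call(cbind, heads) %*% params$W_o, params$b_o)
  out <- layer_norm(queries + att, params$ln_g %||% rep(1, d),
                    params$ln_b %||% numeric(d))
  attr(out, "weights") <- wsum / n_heads
  out
}

layer_norm <- function(x, gain, bias, eps = 1e-5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  sweep(sweep(xc * inv, 2, gain, "*"), 2, bias, "+")
}

#' Encode one channel's token set with the aggregator-GRU recurrence
#'
#' Runs `k + 1` recurrence steps from a zero hidden state: at each step
#' the patch-global aggregator (conditioned on the current hidden
#' state) blends the tokens into a step input, which a GRU cell folds
#' into the next hidden state. With `use_aggregator = FALSE` the tokens
#' are consumed in order (global token last) instead.
#'
#' @param tokens `(k+1) x d` token matrix.
#' @param params List with `w_e` (length `2d`) and the [gru_cell()]
#'   parameter matrices.
#' @param use_aggregator Logical ablation switch.
#' @return `(k+1) x d` matrix of hidden states `h_1 .. h_{k+1}`.
#' @export
encode_channel <- function(tokens, params, use_aggregator = TRUE) {
  kt <- nrow(tokens)
  d <- ncol(tokens)
  h <- numeric(d)
  out <- matrix(0, kt, d)
  for (t in seq_len(kt)) {
    p_t <- if (use_aggregator) {
      aggregate_step(tokens, h, params$w_e)$p_tilde
    } else {
      tokens[t, ]
    }
    h <- gru_cell(p_t, h, params)
    out[t, ] <- h
  }
  out
}
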