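# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape of nodes is built during the forward pass; each node stores its
# value, its parent nodes and a backward closure mapping the node's
# output gradient to parent gradients. Children are always created
# after their parents, so backpropagation is a single reverse sweep in
# creation order. Everything is dense base-R matrices, sized for the
# desk-scale configurations this package trains (feature dimensions in
# the tens to low hundreds).

ad_tape_new <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node$id <- tape$n
  tape$nodes[[tape$n]] <- node
  node
}

ad_value <- function(x) if (is.environment(x)) x$value else x

ad_const <- function(tape, value) ad_node(tape, value)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

# run the backward sweep from a scalar loss node; returns invisibly,
# gradients accumulate in node$grad (read leaf nodes afterwards)
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(grads)) {
      if (!is.null(grads[[j]])) ad_accum(node$parents[[j]], grads[[j]])
    }
  }
  invisible(NULL)
}

## ---- primitive ops ------------------------------------------------------

ad_matmul <- function(tape, a, b) {
  v <- a$value %*% b$value
  ad_node(tape, v, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b),
          function(g) list(g * b$value, g * a$value))
}

# add a 1 x d bias row to every row of a B x d matrix
ad_add_bias <- function(tape, a, bias) {
  v <- sweep(a$value, 2, as.numeric(bias$value), "+")
  ad_node(tape, v, list(a, bias), function(g) {
    list(g, matrix(colSums(g), 1))
  })
}

# multiply each row of a B x d matrix by the matching entry of a B x 1 column
ad_mul_col <- function(tape, a, col) {
  cv <- as.numeric(col$value)
  ad_node(tape, a$value * cv, list(a, col), function(g) {
    list(g * cv, matrix(rowSums(g * a$value), ncol = 1))
  })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(g) list(g * s))
}

ad_one_minus <- function(tape, a) {
  ad_node(tape, 1 - a$value, list(a), function(g) list(-g))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_node(tape, v, list(a), function(g) list(g * (1 - v^2)))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(tape, v, list(a), function(g) list(g * v * (1 - v)))
}

# row-wise softmax of a B x k matrix
ad_softmax_rows <- function(tape, a) {
  x <- a$value
  x <- x - apply(x, 1, max)
  e <- exp(x)
  v <- e / rowSums(e)
  ad_node(tape, v, list(a), function(g) {
    dot <- rowSums(g * v)
    list(v * (g - dot))
  })
}

ad_concat_cols <- function(tape, nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  v <- do.call(cbind, lapply(nodes, function(n) n$value))
  ends <- cumsum(widths)
  starts <- ends - widths + 1
  ad_node(tape, v, nodes, function(g) {
    lapply(seq_along(nodes), function(j) g[, starts[j]:ends[j], drop = FALSE])
  })
}

ad_cols <- function(tape, a, idx) {
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[, idx] <- g
    list(out)
  })
}

# rowSums(a * b) as a B x 1 column (the batched dot product)
ad_rowdot <- function(tape, a, b) {
  v <- matrix(rowSums(a$value * b$value), ncol = 1)
  ad_node(tape, v, list(a, b), function(g) {
    gv <- as.numeric(g)
    list(a$value * 0 + gv * b$value, b$value * 0 + gv * a$value)
  })
}

# row-wise layer normalization with learned gain/bias (1 x d each)
ad_layernorm <- function(tape, a, gain, bias, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gn <- as.numeric(gain$value); bn <- as.numeric(bias$value)
  v <- sweep(sweep(xhat, 2, gn, "*"), 2, bn, "+")
  ad_node(tape, v, list(a, gain, bias), function(g) {
    gxhat <- sweep(g, 2, gn, "*")
    s1 <- rowMeans(gxhat)
    s2 <- rowMeans(gxhat * xhat)
    gx <- inv * (gxhat - s1 - xhat * s2)
    list(gx, matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
  })
}

# mean squared error against a constant target matrix/array
ad_mse <- function(tape, pred, target) {
  diff <- pred$value - target
  n <- length(diff)
  v <- matrix(sum(diff^2) / n, 1, 1)
  ad_node(tape, v, list(pred), function(g) {
    list((2 / n) * diff * as.numeric(g))
  })
}

# sum of scalar loss nodes
ad_sum_scalars <- function(tape, nodes) {
  v <- matrix(sum(vapply(nodes, function(n) n$value[1, 1], numeric(1))), 1, 1)
  ad_node(tape, v, nodes, function(g) {
    lapply(nodes, function(n) g)
  })
}

# replicate the rows of a B x d matrix `times` times (gradient sums blocks)
ad_tile_rows <- function(tape, a, times) {
  b <- nrow(a$value)
  v <- a$value[rep(seq_len(b), times), , drop = FALSE]
  ad_node(tape, v, list(a), function(g) {
    out <- g[seq_len(b), , drop = FALSE]
    for (t in seq_len(times - 1)) {
      out <- out + g[t * b + seq_len(b), , drop = FALSE]
    }
    list(out)
  })
}
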