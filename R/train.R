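# Training loop: Adam on the summed per-target MSE (normalized scale),
# per-epoch train/validation loss logging, best-validation-epoch weight
# retention, fully seeded.

#' Training configuration
#'
#' Defaults follow the published training recipe (Adam, learning rate
#' 0.001, batch size 128, MSE loss); the epoch default is the
#' desk-scale smoke value — pass `epochs = 100` for the full recipe.
#'
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Minibatch size (>= 1).
#' @param epochs Training epochs (>= 0).
#' @param seed Integer seed for shuffling.
#' @param freeze_embedding When fine-tuning, keep the embedding
#'   projections fixed and update only the encoder and heads.
#' @return An `rhp_train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128,
                         epochs = 8, seed = 1, freeze_embedding = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = "mse",
                 seed = as.integer(seed),
                 freeze_embedding = isTRUE(freeze_embedding)),
            class = "rhp_train_config")
}

adam_state_new <- function(P) {
  list(m = lapply(P, function(x) x * 0), v = lapply(P, function(x) x * 0), t = 0)
}

adam_update <- function(P, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(P)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    P[[nm]] <- P[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(P = P, st = st)
}

loss_and_grads <- function(model, inputs, targets) {
  tape <- ad_tape_new()
  Pn <- params_to_nodes(tape, model$params)
  outs <- if (inherits(model, "rhp_baseline")) {
    baseline_forward_tape(tape, Pn, inputs, model)
  } else {
    ea <- list(env = inputs[, , 1:3, drop = FALSE], aux = inputs[, , 4:6, drop = FALSE])
    model_forward_tape(tape, Pn, ea$env, ea$aux, model$config)
  }
  losses <- lapply(seq_len(3), function(i) {
    ad_mse(tape, outs[[i]], matrix(targets[, , i], dim(targets)[1]))
  })
  total <- ad_sum_scalars(tape, losses)
  ad_backward(tape, total)
  grads <- lapply(Pn, function(n) n$grad)
  list(loss = total$value[1, 1], grads = grads)
}

eval_loss <- function(model, windows, batch_size = 256) {
  S <- n_windows(windows)
  tot <- 0
  for (chunk in split(seq_len(S), ceiling(seq_len(S) / batch_size))) {
    pred <- predict(model, subset_windows(windows, chunk))
    tgt <- windows$targets[chunk, , , drop = FALSE]
    tot <- tot + sum(vapply(seq_len(3), function(i) {
      mean((pred[, , i] - tgt[, , i])^2)
    }, numeric(1))) * length(chunk)
  }
  tot / S
}

#' Train a forecaster
#'
#' Minibatch Adam on the sum of the three per-target MSEs (normalized
#' scale). Logs train and validation loss per epoch and returns the
#' weights from the best-validation epoch. Deterministic given the
#' config seed. Aborts with a diagnostic if the loss goes non-finite.
#'
#' @param model An `rhp_model` or `rhp_baseline`.
#' @param train_windows,val_windows `rhp_windows` batches (normalized).
#' @param config An [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained model; `model$history` is a tibble
#'   `(epoch, train_loss, val_loss)` and `model$best_epoch` the epoch
#'   whose weights are retained.
#' @export
train_model <- function(model, train_windows, val_windows,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "rhp_train_config"))
  check_window_shapes(model$config, train_windows)
  check_window_shapes(model$config, val_windows)
  if (n_windows(train_windows) == 0 || n_windows(val_windows) == 0) {
    abort("empty window set")
  }
  if (config$epochs == 0) {
    model$history <- tibble(epoch = integer(), train_loss = double(),
                            val_loss = double())
    return(model)
  }
  set.seed(config$seed)
  st <- adam_state_new(model$params)
  S <- n_windows(train_windows)
  history <- vector("list", config$epochs)
  best_val <- Inf; best_params <- model$params; best_epoch <- 0L

  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(S)
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      lg <- loss_and_grads(model, train_windows$inputs[b, , , drop = FALSE],
                           train_windows$targets[b, , , drop = FALSE])
      if (!is.finite(lg$loss)) {
        abort(sprintf("training diverged at epoch %d (non-finite loss); try a lower learning rate", ep))
      }
      if (isTRUE(config$freeze_embedding)) {
        frozen <- grepl("^(patch_|glob_|aux_)", names(lg$grads))
        lg$grads[frozen] <- list(NULL)
      }
      upd <- adam_update(model$params, lg$grads, st, config$learning_rate)
      model$params <- upd$P
      st <- upd$st
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    ep_loss <- ep_loss / S
    val_loss <- eval_loss(model, val_windows)
    if (!is.finite(val_loss)) abort(sprintf("validation loss non-finite at epoch %d", ep))
    history[[ep]] <- tibble(epoch = ep, train_loss = ep_loss, val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss; best_params <- model$params; best_epoch <- ep
    }
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, ep_loss, val_loss))
    }
  }
  model$params <- best_params
  model$best_epoch <- best_epoch
  model$history <- bind_rows(history)
  model$trained <- TRUE
  model
}

#' Evaluate a model on test windows, on physical scales
#'
#' Predictions and targets are denormalized through the supplied
#' normalization state before MAE/RMSE/R-squared are computed per
#' target.
#'
#' @param model A trained `rhp_model` or `rhp_baseline`.
#' @param test_windows Normalized `rhp_windows`.
#' @param norm_state The [fit_normalizer()] state used to normalize the
#'   data.
#' @param r2_form Passed to [r_squared()].
#' @return A [metrics_report()] tibble.
#' @export
evaluate <- function(model, test_windows, norm_state, r2_form = "standard") {
  check_norm_state(NULL, norm_state)
  pred <- predict(model, test_windows)
  evaluate_forecast(pred, test_windows, norm_state, r2_form)
}

#' Score a precomputed forecast array (e.g. the persistence baseline)
#' @param pred `S x H x 3` normalized forecast array.
#' @inheritParams evaluate
#' @export
evaluate_forecast <- function(pred, test_windows, norm_state, r2_form = "standard") {
  check_norm_state(NULL, norm_state)
  if (!isTRUE(test_windows$normalized)) {
    warn("test windows do not look normalized; denormalizing anyway")
  }
  pred_phys <- denorm_array(pred, norm_state)
  obs_phys <- denorm_array(test_windows$targets, norm_state)
  metrics_report(pred_phys, obs_phys, r2_form)
}
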