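# Experiment harnesses: the input/output length sweep, the module
# ablation study and the cross-region pretrain/fine-tune transfer
# protocol. All are reproducible end-to-end from (config, seed) and
# emit tidy tibbles.

#' Run the standard preprocessing chain on a raw series
#'
#' Outlier masking, bounded-gap interpolation, block-mean down-sampling
#' to the working cadence, chronological 6:1:3 split, and normalization
#' fitted on the training portion only.
#'
#' @param raw A raw sensor table.
#' @param downsample Block length for [downsample_mean()] (default 10).
#' @param ratios Split ratios, default `c(6, 1, 3)`.
#' @param outlier_window,z_threshold Passed to [detect_outliers()].
#' @param max_gap_minutes Passed to [fill_gaps()].
#' @return List with normalized `train`, `val`, `test` tables, the
#'   `norm_state`, and the cleaned full table (`clean`).
#' @export
preprocess_pipeline <- function(raw, downsample = 10, ratios = c(6, 1, 3),
                                outlier_window = 61, z_threshold = 3,
                                max_gap_minutes = 60) {
  masked <- detect_outliers(raw, outlier_window, z_threshold)
  clean <- fill_gaps(masked, max_gap_minutes)
  clean <- downsample_mean(clean, downsample)
  splits <- chronological_split(clean, ratios)
  norm_state <- fit_normalizer(splits$train)
  list(train = normalize(splits$train, norm_state),
       val = normalize(splits$val, norm_state),
       test = normalize(splits$test, norm_state),
       norm_state = norm_state, clean = clean)
}

windows_for <- function(pipeline, n_input, horizon) {
  lapply(pipeline[c("train", "val", "test")], make_windows,
         n_input = n_input, horizon = horizon)
}

train_and_score <- function(model_cfg, pipeline, tc, r2_form = "standard") {
  w <- windows_for(pipeline, model_cfg$n_input, model_cfg$horizon)
  model <- build_model(model_cfg)
  model <- train_model(model, w$train, w$val, tc)
  list(model = model,
       report = evaluate(model, w$test, pipeline$norm_state, r2_form))
}

#' Input/output sequence-length sweep
#'
#' Trains and scores one model per (N, H) grid cell (the full published
#' grid is 7 input lengths x 3 horizons = 21 cells). Cells whose data
#' cannot supply a single window are reported with a skip reason
#' instead of failing the sweep.
#'
#' @param pipeline A [preprocess_pipeline()] result.
#' @param n_values Input lengths N. Default `c(6, 12, 24, 48, 72, 96, 144)`.
#' @param h_values Horizons H. Default `c(6, 12, 24)`.
#' @param model_config Base [rhp_config()]; N and H are overridden per cell.
#' @param config A [train_config()].
#' @return A tidy tibble with one row per (N, H, target):
#'   `n_input, horizon, target, mae, rmse, r2, status`.
#' @export
length_sweep <- function(pipeline, n_values = c(6, 12, 24, 48, 72, 96, 144),
                         h_values = c(6, 12, 24),
                         model_config = rhp_config_smoke(),
                         config = train_config()) {
  grid <- tidyr::expand_grid(n_input = n_values, horizon = h_values)
  purrr::pmap_dfr(grid, function(n_input, horizon) {
    cell <- tryCatch({
      cfg <- modify_config(model_config, n_input = n_input, horizon = horizon)
      res <- train_and_score(cfg, pipeline, config)
      res$report %>%
        select("target", "mae", "rmse", "r2") %>%
        mutate(status = "ok")
    }, error = function(e) {
      tibble(target = rhp_env_channels(), mae = NA_real_, rmse = NA_real_,
             r2 = NA_real_, status = paste("skipped:", conditionMessage(e)))
    })
    mutate(cell, n_input = n_input, horizon = horizon, .before = 1)
  })
}

modify_config <- function(cfg, ...) {
  fields <- list(...)
  args <- list(n_input = cfg$n_input, horizon = cfg$horizon,
               patch_len = cfg$patch_len, d = cfg$d, n_layers = cfg$n_layers,
               n_heads = cfg$n_heads, ffn_hidden = cfg$ffn_hidden,
               use_patch_encoding = cfg$use_patch_encoding,
               use_aggregator = cfg$use_aggregator,
               use_cross_attention = cfg$use_cross_attention,
               n_aux = cfg$n_aux, seed = cfg$seed)
  do.call(rhp_config, modifyList(args, fields))
}

#' Module ablation study
#'
#' Trains the full model and the three single-module-off variants under
#' identical data and seeds, mirroring the published ablation layout.
#'
#' @inheritParams length_sweep
#' @param seeds Integer vector of seeds; each configuration is trained
#'   once per seed and rows are emitted per seed.
#' @return Tibble with columns `variant, use_patch_encoding,
#'   use_aggregator, use_cross_attention, seed, n_parameters, target,
#'   mae, rmse, r2`.
#' @export
ablation_study <- function(pipeline, model_config = rhp_config_smoke(),
                           config = train_config(), seeds = model_config$seed) {
  variants <- tibble::tribble(
    ~variant,            ~use_patch_encoding, ~use_aggregator, ~use_cross_attention,
    "no_patch_encoding", FALSE,               TRUE,            TRUE,
    "no_aggregator",     TRUE,                FALSE,           TRUE,
    "no_cross_attention",TRUE,                TRUE,            FALSE,
    "full",              TRUE,                TRUE,            TRUE
  )
  purrr::pmap_dfr(variants, function(variant, use_patch_encoding,
                                     use_aggregator, use_cross_attention) {
    purrr::map_dfr(seeds, function(s) {
      cfg <- modify_config(model_config,
                           use_patch_encoding = use_patch_encoding,
                           use_aggregator = use_aggregator,
                           use_cross_attention = use_cross_attention,
                           seed = s)
      tc <- config; tc$seed <- s
      res <- train_and_score(cfg, pipeline, tc)
      res$report %>%
        select("target", "mae", "rmse", "r2") %>%
        mutate(variant = variant,
               use_patch_encoding = use_patch_encoding,
               use_aggregator = use_aggregator,
               use_cross_attention = use_cross_attention,
               seed = s, n_parameters = n_parameters(res$model),
               .before = 1)
    })
  })
}

#' Cross-region pretrain / fine-tune transfer protocol
#'
#' Pretrains the model on each source dataset (and on all sources
#' combined), then, together with a random initialization, evaluates
#' each on the target test set zero-shot and after fine-tuning on six
#' nested chronological prefixes (10%-60%) of the target training
#' partition. Validation and test partitions stay fixed throughout.
#'
#' @param source_pipelines Named list of [preprocess_pipeline()] results
#'   for the source regions.
#' @param target_pipeline [preprocess_pipeline()] result for the target
#'   region (its 6:1:3 split is reused).
#' @param model_config Base [rhp_config()].
#' @param config [train_config()] used for both pretraining and
#'   fine-tuning (all weights updated at the base learning rate).
#' @param subset_fractions Nested fine-tuning fractions of the target
#'   training rows. Default `seq(0.1, 0.6, by = 0.1)`.
#' @return Tibble with one row per (initialization, subset, target):
#'   `init, subset, frac, n_train_windows, target, mae, rmse, r2`.
#'   `subset = 0` rows are the zero-shot evaluations.
#' @export
transfer_protocol <- function(source_pipelines, target_pipeline,
                              model_config = rhp_config_smoke(),
                              config = train_config(),
                              subset_fractions = seq(0.1, 0.6, by = 0.1)) {
  stopifnot(length(source_pipelines) >= 1, !is.null(names(source_pipelines)))
  for (nm in names(source_pipelines)) {
    if (isTRUE(all.equal(source_pipelines[[nm]]$clean[, rhp_channels()],
                         target_pipeline$clean[, rhp_channels()]))) {
      abort(sprintf("source dataset '%s' is identical to the target dataset; sources and target must be disjoint", nm))
    }
  }
  N <- model_config$n_input; H <- model_config$horizon
  tgt <- windows_for(target_pipeline, N, H)

  pretrain_on <- function(train_w, val_w) {
    m <- build_model(model_config)
    train_model(m, train_w, val_w, config)
  }
  src_windows <- lapply(source_pipelines, windows_for, n_input = N, horizon = H)
  inits <- list(init = build_model(model_config))
  for (nm in names(src_windows)) {
    inits[[nm]] <- pretrain_on(src_windows[[nm]]$train, src_windows[[nm]]$val)
  }
  if (length(src_windows) > 1) {
    comb_train <- Reduce(concat_windows, lapply(src_windows, `[[`, "train"))
    comb_val <- Reduce(concat_windows, lapply(src_windows, `[[`, "val"))
    inits[[paste(names(src_windows), collapse = "+")]] <-
      pretrain_on(comb_train, comb_val)
  }

  n_target_rows <- nrow(target_pipeline$train)
  purrr::imap_dfr(inits, function(model0, init_name) {
    zero_shot <- evaluate(model0, tgt$test, target_pipeline$norm_state) %>%
      select("target", "mae", "rmse", "r2") %>%
      mutate(init = init_name, subset = 0L, frac = 0,
             n_train_windows = 0L, .before = 1)
    tuned <- purrr::imap_dfr(subset_fractions, function(frac, k) {
      rows <- seq_len(as.integer(round_half_up(frac * n_target_rows)))
      sub_tab <- target_pipeline$train[rows, ]
      sub_tab <- set_step_minutes(sub_tab, series_step_minutes(target_pipeline$train))
      rep_k <- tryCatch({
        sub_w <- make_windows(sub_tab, N, H)
        m <- train_model(model0, sub_w, tgt$val, config)
        evaluate(m, tgt$test, target_pipeline$norm_state) %>%
          select("target", "mae", "rmse", "r2") %>%
          mutate(n_train_windows = n_windows(sub_w), .before = 1)
      }, error = function(e) {
        tibble(n_train_windows = 0L, target = rhp_env_channels(),
               mae = NA_real_, rmse = NA_real_, r2 = NA_real_)
      })
      mutate(rep_k, init = init_name, subset = k, frac = frac, .before = 1)
    })
    bind_rows(zero_shot, tuned)
  })
}
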