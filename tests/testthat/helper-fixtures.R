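# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 14-day minute-resolution Fujian series, no artifacts
fujian_14d <- function() {
  fixture("fujian_14d", function() {
    simulate_house(make_region_preset("fujian"), sim_config(n_days = 14, seed = 7))
  })
}

# the same series with seeded spikes and two gaps (30 min imputable,
# 90 min -> segment break)
fujian_14d_dirty <- function() {
  fixture("fujian_14d_dirty", function() {
    cfg <- sim_config(n_days = 14, seed = 7, outlier_rate = 0.01,
                      gap_spec = list(c(3000L, 30), c(9000L, 90)))
    inject_artifacts(fujian_14d(), cfg)
  })
}

# preprocessed 10-minute pipeline of the clean series
fujian_pipeline <- function() {
  fixture("fujian_pipeline", function() preprocess_pipeline(fujian_14d()))
}

# small 4-day pipelines for harness-shape tests
small_pipeline <- function(region = "fujian", seed = 11) {
  fixture(paste0("small_", region, "_", seed), function() {
    preprocess_pipeline(simulate_house(make_region_preset(region),
                                       sim_config(n_days = 4, seed = seed)))
  })
}

tiny_train_config <- function(epochs = 1, seed = 1) {
  train_config(epochs = epochs, seed = seed)
}

tiny_model_config <- function(...) {
  rhp_config_smoke(d = 16, ffn_hidden = 32, ...)
}
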