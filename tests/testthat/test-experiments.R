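test_that("error metrics follow their definitions and ordering", {
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, 3), c(2, 2)), 1)
  expect_equal(rmse(c(1, 3), c(2, 2)), 1)
  expect_equal(mae(c(0, 4), c(0, 0)), 2)
  expect_equal(rmse(c(0, 4), c(0, 0)), sqrt(8))
  expect_gte(rmse(c(0, 4), c(0, 0)), mae(c(0, 4), c(0, 0)))
  expect_error(mae(numeric(), numeric()), "empty")

  # RMSE >= MAE on random pairs
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_gte(rmse(a, b), mae(a, b))
  }
})

test_that("both R-squared dialects behave as defined", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, y, form = "printed"), 1)
  ybar <- rep(mean(y), 3)
  expect_equal(r_squared(ybar, y), 0)
  expect_equal(r_squared(ybar, y, form = "printed"), 0)
  yp <- c(1, 2, 4)
  expect_equal(r_squared(yp, y, form = "standard"), 0.5)
  expect_equal(r_squared(yp, y, form = "printed"), 2.5)
  expect_error(r_squared(yp, c(2, 2, 2)), "constant")
})

test_that("improvement percentages reproduce the published comparison table", {
  # model-vs-best-baseline decreases (one decimal)
  expect_equal(improvement_pct(0.476, 0.290), 39.1)  # temperature RMSE
  expect_equal(improvement_pct(0.370, 0.220), 40.5)  # temperature MAE
  expect_equal(improvement_pct(1.836, 1.554), 15.4)  # humidity RMSE
  expect_equal(improvement_pct(1.273, 1.052), 17.4)  # humidity MAE
  expect_equal(improvement_pct(39.506, 38.837), 1.7) # CO2 RMSE
  expect_equal(improvement_pct(29.706, 25.269), 14.9)# CO2 MAE
  expect_equal(improvement_pct(5, 5), 0)
  expect_error(improvement_pct(0, 1), "positive")
})

test_that("ablation increases reproduce the published percentages", {
  # increase form: 100 * (ablated - full) / full, nearest integer
  expect_equal(improvement_pct(0.290, 0.643, form = "increase"), 122)
  expect_equal(improvement_pct(1.554, 2.534, form = "increase"), 63)
  expect_equal(improvement_pct(38.837, 50.215, form = "increase"), 29)
  expect_equal(improvement_pct(0.290, 0.365, form = "increase"), 26)
  expect_equal(improvement_pct(1.554, 1.780, form = "increase"), 15)
})

test_that("training reduces the loss, is seeded, and epochs 0 is a no-op", {
  pl <- small_pipeline()
  w <- lapply(pl[c("train", "val", "test")], make_windows, n_input = 12, horizon = 6)
  cfg <- tiny_model_config(n_input = 12, horizon = 6, seed = 2)
  m0 <- build_model(cfg)
  m1 <- train_model(m0, w$train, w$val, tiny_train_config(epochs = 3, seed = 2))
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  m2 <- train_model(m0, w$train, w$val, tiny_train_config(epochs = 3, seed = 2))
  expect_identical(m1$history, m2$history)  # identical seeded traces
  m3 <- train_model(m0, w$train, w$val, tiny_train_config(epochs = 0))
  expect_identical(m3$params, m0$params)
  expect_equal(nrow(m3$history), 0)
})

test_that("evaluation reports physical scales and rejects normalized observations", {
  pl <- small_pipeline()
  w <- make_windows(pl$test, 12, 6)
  # a perfect oracle scores perfectly
  rep0 <- evaluate_forecast(w$targets, w, pl$norm_state)
  expect_equal(rep0$mae, rep(0, 3))
  expect_equal(rep0$rmse, rep(0, 3))
  expect_equal(rep0$r2, rep(1, 3))
  # persistence is finite with RMSE >= MAE, on physical scales
  pers <- evaluate_forecast(persistence_forecast(w), w, pl$norm_state)
  expect_true(all(is.finite(pers$rmse)))
  expect_true(all(pers$rmse >= pers$mae))
  expect_gt(max(pers$rmse), 1)  # CO2 in ppm: clearly not unit-scaled
  # feeding normalized targets straight into the metric layer raises
  expect_error(metrics_report(w$targets, w$targets), "normalized")
})

test_that("the length sweep emits one row per grid cell and target", {
  pl <- small_pipeline()
  res <- length_sweep(pl, n_values = c(12, 24), h_values = c(6, 12),
                      model_config = tiny_model_config(n_input = 12, horizon = 6),
                      config = tiny_train_config())
  expect_equal(nrow(res), 2 * 2 * 3)
  expect_true(all(c("n_input", "horizon", "target", "mae", "rmse", "r2", "status")
                  %in% names(res)))
  expect_true(all(res$status == "ok"))
  # an impossible cell is skipped with a reason, not an error
  res2 <- length_sweep(pl, n_values = c(100000), h_values = c(6),
                       model_config = tiny_model_config(n_input = 12, horizon = 6),
                       config = tiny_train_config())
  expect_equal(nrow(res2), 3)
  expect_true(all(grepl("skipped", res2$status)))
})

test_that("transfer protocol rejects a source identical to the target", {
  pl <- small_pipeline()
  expect_error(transfer_protocol(list(clone = pl), pl,
                                 tiny_model_config(n_input = 12, horizon = 6),
                                 tiny_train_config()),
               "disjoint")
})
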