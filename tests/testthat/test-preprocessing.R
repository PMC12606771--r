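make_flat_table <- function(n = 200, value = 20) {
  ts <- as.POSIXct("2023-08-20", tz = "UTC") + 60 * (seq_len(n) - 1)
  tab <- tibble::tibble(timestamp = ts, Tin = value, RHin = 70, CO2 = 900,
                        WS = 1, Tout = 25, RHout = 80)
  attr(tab, "step_minutes") <- 1
  tab
}

test_that("a single spike in a constant background is masked, nothing else", {
  tab <- make_flat_table()
  tab$Tin[100] <- 20 + 10
  out <- detect_outliers(tab, window = 61, z_threshold = 3)
  expect_true(is.na(out$Tin[100]))
  expect_equal(sum(is.na(out$Tin)), 1)
  expect_false(anyNA(out$RHin))
  # unmasked values are never altered
  expect_equal(out$Tin[-100], tab$Tin[-100])
})

test_that("detector has perfect recall on injected spikes and low false-positive rate", {
  dirty <- fujian_14d_dirty()
  out <- detect_outliers(dirty, window = 61, z_threshold = 3)
  log <- artifact_log(dirty)
  spikes <- log[log$kind == "spike", ]
  hit <- mapply(function(r, ch) is.na(out[[ch]][r]), spikes$row, spikes$channel)
  expect_equal(mean(hit), 1)  # 100% recall on 6-robust-SD spikes

  # false positives on clean noise-free diurnal curves: the detector
  # must not fire on smooth trend alone
  p0 <- make_region_preset("fujian")
  p0$noise_sd[] <- 0; p0$ar_coefficient <- 0
  clean0 <- simulate_house(p0, sim_config(n_days = 7, seed = 1))
  masked0 <- attr(detect_outliers(clean0, 61, 3), "outlier_mask")
  expect_lt(nrow(masked0) / (nrow(clean0) * 6), 0.01)
})

test_that("gap interpolation follows y_k = y1 + k/(n+1) (y2 - y1)", {
  tab <- make_flat_table(20)
  tab$Tin <- c(0, NA, NA, NA, 4, rep(4, 15))
  clean <- fill_gaps(tab)
  expect_equal(clean$Tin[2:4], c(1, 2, 3))

  tab$Tin <- c(5, NA, NA, NA, 5, rep(5, 15))
  expect_equal(fill_gaps(tab)$Tin[2:4], c(5, 5, 5))
})

test_that("gaps over 60 minutes become segment breaks, not imputations", {
  tab <- make_flat_table(300)
  tab$Tin[100:160] <- NA  # 61-minute run at 1-min step
  clean <- fill_gaps(tab)
  expect_false(any(clean$timestamp %in% tab$timestamp[100:160]))
  expect_equal(sort(unique(clean$segment)), c(1, 2))
  breaks <- attr(clean, "segment_breaks")
  expect_equal(breaks$row_start, 100)
  expect_equal(breaks$row_end, 160)

  # exactly 60 minutes is still imputable
  tab2 <- make_flat_table(300)
  tab2$Tin[100:159] <- NA
  clean2 <- fill_gaps(tab2)
  expect_equal(unique(clean2$segment), 1)
  expect_false(anyNA(clean2$Tin))
})

test_that("block-mean down-sampling averages non-overlapping blocks", {
  tab <- make_flat_table(100)
  tab$Tin <- seq_len(100)
  clean <- fill_gaps(tab)
  ds <- downsample_mean(clean, 10)
  expect_equal(nrow(ds), 10)
  expect_equal(ds$Tin[1], mean(1:10))  # 5.5
  expect_equal(ds$Tin[10], mean(91:100))
  expect_equal(attr(ds, "step_minutes"), 10)
  expect_identical(downsample_mean(clean, 1), clean)
  expect_error(downsample_mean(clean, 0), "positive")

  # 7 days at 1-min step -> 1008 ten-minute points
  week <- fill_gaps(fujian_14d()[1:10080, ])
  expect_equal(nrow(downsample_mean(week, 10)), 1008)
})

test_that("min-max normalization follows the epsilon-guarded formula and inverts", {
  tab <- make_flat_table(50)
  tab$Tin <- seq(2, 8, length.out = 50)
  state <- fit_normalizer(tab)
  expect_equal(state$xmin[state$channel == "Tin"], 2)
  expect_equal(state$xmax[state$channel == "Tin"], 8)
  expect_identical(fit_normalizer(tab), state)

  norm <- normalize(tab, state)
  expect_equal(norm$Tin[1], 0)  # x = xmin
  expect_equal(max(norm$Tin), 6 / (6 + 1e-7))
  # constant channel -> all zeros, and the round trip still inverts
  expect_true(all(norm$WS == 0))
  back <- denormalize(norm, state)
  for (ch in rhp_channels()) {
    expect_lt(max(abs(back[[ch]] - tab[[ch]])) / max(abs(tab[[ch]])), 1e-9)
  }
  # direct substitution: xmin 0, xmax 1, x 1
  tab2 <- make_flat_table(10)
  tab2$Tin <- seq(0, 1, length.out = 10)
  st2 <- fit_normalizer(tab2)
  expect_equal(normalize(tab2, st2)$Tin[10], 1 / (1 + 1e-7))
})

test_that("chronological split reproduces the published sizes and never leaks", {
  expect_equal(unname(chronological_split(7548)), c(4529, 755, 2264))
  expect_equal(unname(chronological_split(10)), c(6, 1, 3))
  expect_equal(unname(chronological_split(100)), c(60, 10, 30))
  expect_error(chronological_split(9), "at least 10")

  for (m in c(17, 101, 999, 7548)) {
    s <- split_sizes(m)
    expect_equal(sum(s), m)
  }

  pl <- fill_gaps(fujian_14d()[1:3000, ])
  sp <- chronological_split(pl)
  expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(pl))
  expect_true(max(sp$train$timestamp) < min(sp$val$timestamp))
  expect_true(max(sp$val$timestamp) < min(sp$test$timestamp))
})

test_that("windows are stride-1, segment-bounded and correctly counted", {
  tab <- make_flat_table(300)
  tab$Tin <- rnorm(300)
  clean <- fill_gaps(tab)
  w <- make_windows(clean, 48, 12)
  expect_equal(n_windows(w), 300 - 48 - 12 + 1)
  expect_equal(dim(w$inputs), c(241, 48, 6))
  expect_equal(dim(w$targets), c(241, 12, 3))
  # target window immediately follows the input window
  expect_equal(w$targets[1, , "Tin"], clean$Tin[49:60])
  expect_equal(unname(w$inputs[2, 1, "Tin"]), clean$Tin[2])

  # segment of exactly N + H gives one window
  tabS <- make_flat_table(60)
  wS <- make_windows(fill_gaps(tabS), 48, 12)
  expect_equal(n_windows(wS), 1)

  # two segments (60, 59): the second is too short
  tab2 <- make_flat_table(250)
  tab2$Tin[61:191] <- NA  # long gap splits 60 | 59 usable rows
  clean2 <- fill_gaps(tab2)
  lens <- table(clean2$segment)
  expect_equal(unname(as.integer(lens)), c(60, 59))
  w2 <- make_windows(clean2, 48, 12)
  expect_equal(n_windows(w2), 1)
  expect_true(all(w2$index$segment == 1))
  expect_error(make_windows(clean2, 100, 12), "112")
})
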