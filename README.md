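# rhpcast

Short-horizon forecasting of rabbit-house microclimate — indoor air
temperature (°C), relative humidity (%) and CO₂ concentration (ppm) —
from multivariate sensor series, for researchers and engineers building
predictive environmental control in intensive rabbit farming.

Enclosed livestock houses respond to ventilation and cooling actions
with a lag, so regulation based on current readings alone under- and
over-shoots; a 2-hour forecast of the indoor climate lets the
controller anticipate instead. `rhpcast` implements a patch- and
cross-attention-based multivariate, multi-step forecaster together with
everything around it: a seeded synthetic barn-microclimate simulator,
the preprocessing chain, recurrent baselines, and experiment harnesses
for length sweeps, module ablations and cross-region transfer.

## The model

An input window of N ten-minute steps per target channel is cut into
k = N/L non-overlapping patches. Patches and the whole sequence are
embedded separately (a global token p_G alongside p₁…p_k, with
sinusoidal positional encodings), so the encoder sees both local trend
and whole-window shape. Each encoder layer then runs, per target
channel:

1. **Patch–Global Aggregator + GRU** — from h₀ = 0, at each step the
   tokens are scored against the hidden state,
   e_tj = tanh(w_e·[h_{t−1}; p_j]), softmax-weighted into
   p̃_t = Σⱼ α_tj p_j, and folded in by a GRU:
   z_t = σ(W_z[h_{t−1}; p̃_t]), r_t = σ(W_r[h_{t−1}; p̃_t]),
   h̃_t = tanh(W[r_t⊙h_{t−1}; p̃_t]),
   h_t = (1−z_t)⊙h_{t−1} + z_t⊙h̃_t.
2. **Cross-attention** — the temporally encoded target tokens are
   queries; channel-encoded auxiliary tokens (indoor wind speed,
   outdoor temperature/humidity) are keys and values:
   softmax(QKᵀ/√d_k)V, residual + layer norm.
3. **Feed-forward** block with residual + layer norm.

Three parallel per-target linear heads map the flattened (k+1)·d
encoder output to the H-step forecast. Training is Adam on MSE
(normalized scale), implemented on the package's own reverse-mode
autodiff tape; forecasts are inverted to physical units before scoring
with MAE, RMSE and R².

## Worked example

```r
library(rhpcast)

# 14 days of synthetic minute-resolution data, coastal-humid preset
preset <- make_region_preset("fujian")
raw <- simulate_house(preset, sim_config(n_days = 14, seed = 7))

# clean -> 10-min cadence -> 6:1:3 split -> leakage-free normalization
pl <- preprocess_pipeline(raw)

# windows: 8 h of history (N = 48), 2 h horizon (H = 12)
w <- lapply(pl[c("train", "val", "test")], make_windows,
            n_input = 48, horizon = 12)

model <- build_model(rhp_config_smoke(n_input = 48, horizon = 12, seed = 1))
model <- train_model(model, w$train, w$val, train_config(seed = 1))

evaluate(model, w$test, pl$norm_state)
#> # A tibble: 3 x 6
#>   target unit     mae   rmse    r2     n
#>   <chr>  <chr>  <dbl>  <dbl> <dbl> <int>
#> 1 Tin    degC   0.284  0.353 0.973  6540
#> 2 RHin   %      1.01   1.26  0.955  6540
#> 3 CO2    ppm   30.1   37.2   0.950  6540

evaluate_forecast(persistence_forecast(w$test), w$test, pl$norm_state)
#> 1 Tin    degC   0.575  0.735 0.881  6540   # naive last-value baseline
```

After eight epochs at the desk-scale profile (d = 32, one encoder
layer) the model forecasts temperature two hours ahead with 0.35 °C
RMSE versus 0.74 °C for the persistence baseline — the trained network
roughly halves the naive error and explains ~97% of the variance on
this synthetic test set. `length_sweep()`, `ablation_study()` and
`transfer_protocol()` run the three experiment harnesses over the same
pipeline objects; `autoplot()`, `plot_sweep()`, `plot_transfer()` and
`plot_training()` draw the standard figures, and `tidy()`/`glance()`
summarise fitted models.

A command-line wrapper ships in `inst/cli/`:

```sh
Rscript inst/cli/rhpcast simulate --region fujian --days 14 --seed 7 --out sim.csv
Rscript inst/cli/rhpcast train --data sim.csv --out-dir run/ --seed 1
```

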