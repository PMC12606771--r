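Package: rhpcast
Title: Multi-Parameter Forecasting of Rabbit-House Microclimate with a
    Patch and Cross-Attention Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for short-horizon forecasting of indoor temperature,
    relative humidity and carbon dioxide concentration in intensive
    rabbit houses. Provides a seeded synthetic barn-microclimate
    simulator with regional presets, a reproducible preprocessing chain
    (Hampel-style sliding-window outlier masking, bounded-gap linear
    interpolation, block-mean down-sampling, reversible min-max
    normalization, chronological splitting and windowing), a patch- and
    cross-attention-based encoder with an attention-weighted GRU
    temporal aggregator trained by a built-in reverse-mode autodiff
    engine, recurrent baselines, and experiment harnesses for
    input/output length sweeps, module ablations and cross-region
    pretrain/fine-tune transfer. All user-facing functions take and
    return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
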