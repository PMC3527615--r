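Package: arcticann
Title: Neural-Network Models of Prokaryotic and Viral Abundance in Arctic
    Seawater
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for developing small regression neural networks
    (feed-forward and radial-basis-function) that predict flow-cytometric
    prokaryotic (high and low nucleic-acid cells) and viral (high- and
    low-fluorescence populations) abundances from oceanographic covariates.
    Implements Levenberg-Marquardt training with a per-iteration train/test
    RMSE record and early stopping at the combined-RMSE minimum, two-phase
    random-restart screening over architectures and input subsets,
    evaluation by observed-versus-predicted regression on an independent
    survey, a stepwise multiple linear regression baseline, solar day-length
    computation at polar latitudes, a calibrated synthetic generator for
    Arctic seasonal and spatial station data, and grid simulations of
    abundance over environmental ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
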