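Package: climsens
Title: Climate Sensitivity Assessment of Species Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for assessing the climate sensitivity of
    species from seasonal presence/absence surveys and monthly climate
    grids. Computes the standard bioclimatic variables (BIO1-BIO19) from
    monthly minimum temperature, maximum temperature and precipitation;
    builds future fine-scale climates by the additive anomaly (delta)
    method; fits per-species boosted regression tree distribution models
    with survey effort or survey date covariates; delineates binary range
    maps with the maximum-Kappa threshold and ensembles projections
    across general circulation models (consensus forecasting); decomposes
    projected change into current-range stability and potential expansion
    and assigns climate endangered / threatened / stable categories;
    and summarizes outcomes via weighted range centroids, per-cell
    species turnover (binary Bray-Curtis dissimilarity), Kendall rank
    correlations with conservation priority schemes, and random-effects
    variance components. Includes a synthetic-data generator (landscapes,
    climates, virtual species with Gaussian niches, survey designs) with
    exact ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
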