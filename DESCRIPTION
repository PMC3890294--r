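Package: mobiscale
Title: Scaling Laws and Displacement Correlations in Human Mobility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for the statistical analysis of human mobility from raw
    GPS trajectories. Extracts effective staying positions (staypoints) from
    Geolife-style PLT tracks using a spatial/temporal dwell rule, builds
    displacement, staying-time and elapsed-time series, fits heavy-tailed
    (power-law) distributions by log-binning, two-regime log-log regression
    and maximum likelihood with Kolmogorov-Smirnov bootstrap confidence,
    and quantifies the serial structure of displacement series with
    Kendall's tau (including its lag decay), log-displacement Pearson
    autocorrelation and detrended fluctuation analysis. Seeded agent-based
    mobility simulators (Levy flight, continuous-time random walk,
    exploration/preferential-return, self-similar least-action walk and a
    hierarchical-traffic-system walker) and synthetic trajectory/series
    generators support model comparison and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
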