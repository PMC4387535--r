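Package: u5map
Title: Model-Based Geostatistical Mapping of Under-Five Population Proportions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the proportion of a population under five years
    of age at fine grid resolution from geolocated household-survey clusters,
    using model-based geostatistics: a separable space-time Gaussian process
    with Matern (nu = 1) spatial covariance, AR(1) survey-wave correlation,
    a nugget measurement-error term and linear covariate effects. Includes a
    synthetic-survey generator emulating displaced cluster centroids and
    environmental covariate rasters, exhaustive best-subset BIC covariate
    selection, maximum marginal-likelihood fitting with Laplace uncertainty,
    universal-kriging prediction surfaces with credible bounds, leave-one-out
    and holdout validation with permutation-envelope semivariograms, and a
    downstream application that converts proportion surfaces into under-five
    count surfaces for comparing intervention-coverage denominators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
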