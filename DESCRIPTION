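Package: shearwaterSDM
Title: Species Distribution Models and Strip-Transect Abundance for At-Sea Seabird Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for vessel-based seabird surveys in shelf
    seas, built around the postbreeding Balearic shearwater (Puffinus
    mauretanicus) surveys of the western English Channel and southern Celtic
    Sea. Provides derivation of bathymetric and tidal covariates (terrain
    ruggedness, seafloor aspect, depth anomalies, the Simpson-Hunter
    stratification index), construction of a 1-km2 analysis grid with
    effort-based false-absence filtering, constrained AIC selection of
    binomial generalized additive models, class-balanced random-forest
    ensembles with leave-one-year-out validation, and strip-transect
    density-multiplication abundance estimation with day-weighted variance.
    A fully seeded synthetic-survey generator with a known habitat-suitability
    surface makes every stage testable and supports parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    randomForest,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
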