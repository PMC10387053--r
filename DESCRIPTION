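Package: rootprod
Title: Fine Root Production from Minirhizotron Depth Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates fine root production (FRP) in tropical forest and
    peatland soils from minirhizotron root-length measurements. Provides a
    compound Poisson-gamma (Tweedie) sampler and maximum-likelihood
    regression with a log link for zero-inflated root-growth rates,
    Type-III Wald chi-square tests, estimated marginal means with Tukey
    post hoc comparisons, LOESS extrapolation of depth profiles over a
    1-m soil column, and conversion of root-length production to annual
    carbon flux (Mg C per hectare per year) with propagated standard
    errors. Includes a calibrated synthetic-data generator emulating a
    3-ecosystem x 16-tube x 3-season x 5-depth minirhizotron campaign,
    packaged reference tables from a Congo Basin field study, and an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB,
    mgcv,
    optparse
Config/testthat/edition: 3
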