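Package: fgym
Title: Climate- and Stage-Sensitive Growth and Yield Modelling for Natural Dahurian Larch Stands
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stand-level forest growth and yield modelling system for natural
    Larix gmelinii (Dahurian larch) secondary forests. Implements a coupled
    equation family -- Richards mean-height and site class index curves, a
    Reineke-type self-thinning line and stand density index dynamics,
    Mitscherlich basal-area models with site, density, climate (De Martonne
    aridity index) and developmental-stage dummy-variable effects, a
    form-factor volume equation, additive allometric biomass equations with
    component carbon fractions -- together with a nine-step stand simulator,
    negative-exponential diameter-class allocation with q-ratio control,
    timber-assortment and commercial/non-commercial carbon partitioning, a
    versioned parameter registry with published defaults, estimation machinery
    (0.99-quantile self-thinning regression and reciprocally weighted
    nonlinear least squares), and a synthetic inventory-plot generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
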