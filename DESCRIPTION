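Package: dnaguv
Title: Thermomechanics of DNA-Mediated Adhesion in Giant Unilamellar Vesicle Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled membrane-mechanics and DNA-hybridization model for pairs of
    adhering giant unilamellar vesicles (GUVs) functionalized with mobile DNA
    tethers. Predicts the equilibrium geometry (contact angle, adhesion patch
    area, centre-to-centre distance, radius, area, volume) and the fractions of
    DNA tethers forming inter-vesicle bridges and intra-vesicle loops as a
    function of temperature, by minimizing a free energy that combines membrane
    stretching elasticity with the mean-field statistical mechanics of mobile
    multivalent linkers. Includes fitting of the single neutral-temperature
    parameter, Monte-Carlo propagation of parameter uncertainty to percentile
    envelopes, fluorescence-based estimators of geometry and bridge fraction,
    and a synthetic-observation generator for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
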