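Package: nutrikin
Title: Emergent Nutrient Transport and Growth Kinetics for Phytoplankton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of phytoplankton nutrient acquisition, from
    transporter proteins in the plasma membrane up to whole-cell growth
    kinetics. Cell geometry, carbon-density allometry (vacuolation), elemental
    stoichiometry (Droop-type normalized N:C quota), transporter rate density,
    Michaelis-Menten transport at the membrane, and diffusive boundary-layer
    gradients enhanced by swimming or Stokes sedimentation are chained to
    compute the bulk-medium substrate concentration that supports any given
    growth rate. The half-saturation constant for growth (K_G) emerges from
    this chain rather than being an input, and the package provides trait
    scans, power-law scaling fits, rectangular-hyperbola (Monod) fits exposing
    the bias of that curve form on emergent kinetics, and synthetic-data
    generators for uptake experiments and nutrient-status-dependent transport
    capacity curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
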