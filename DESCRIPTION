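Package: dietfootprint
Title: Diet Quality, Food Loss and Waste, and Agricultural Resource Footprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links individual-level diet quality (HEI-2015 and a modified
    AHEI-2010) to food loss and waste mass accounting and to agricultural
    resource use (land, fertilizer nutrients, pesticides, irrigation water)
    through a simplified closed-food-system biophysical model. Provides a
    seeded synthetic-survey generator emulating a stratified two-PSU-per-stratum
    design, recipe-based disaggregation of as-consumed foods into commodities,
    back-calculation of retail loss, inedible portions, consumer waste and
    Total Food Demand from consumed mass, design-based (Taylor-linearized)
    survey estimation with quintile trend tests, and Monte Carlo uncertainty
    propagation for the footprint model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
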