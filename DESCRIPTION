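Package: ojipr
Title: JIP-Test Analysis of Fast Chlorophyll-a Fluorescence (OJIP) Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing fast (OJIP) chlorophyll-a fluorescence
    induction curves from dark-adapted leaves: reading and validating
    transient tables, extraction of the cardinal O/J/I/P fluorescence
    points, the full JIP-test parameter system (specific and
    phenomenological energy fluxes, quantum yields, performance index,
    normalized complementary area), per-group energy-pipeline models with
    active/inactive reaction-centre densities, and many-to-one Dunnett
    comparisons against a control group with dose-response threshold
    detection. Includes a seeded generator of synthetic polyphasic
    transients emulating a graded root-cutting stress experiment, so the
    entire pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    readr,
    stats,
    utils,
    tools,
    multcomp,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
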