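Package: chwearn
Title: Scenario Projection of Community Health Worker Incentive Earnings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing performance-based incentive systems for
    community health workers (CHWs), modelled on India's ASHA programme.
    Projects per-incentive monthly earnings under four counterfactual
    scenarios (perfect/actual worker crossed with perfect/actual household),
    converts annual demographic rates into monthly beneficiary incidence per
    catchment, decomposes the difference between potential, achievable,
    modelled-actual and observed government payments into design and
    implementation gaps, fits relaxed completion thresholds for lump-sum
    series incentives against observed payments, estimates rate inputs and
    descriptive statistics from linked household and CHW survey microdata,
    and generates synthetic linked-survey microdata with the statistical
    structure the analysis assumes so that every stage is testable without
    access to the underlying surveys.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
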