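Package: foodaidsim
Title: Microsimulation of Food-Aid Delivery and Cardiometabolic Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level microsimulation linking the delivery mechanism of
    food aid (traditional in-kind parcel, restricted electronic debit card,
    cash, or an alternative parcel with less grain and more fruits and
    vegetables) to nutrient intake, cardiometabolic biomarkers, chronic-disease
    incidence, mortality, and cost-effectiveness in a refugee population.
    Synthetic cohorts with realistic marginals and correlation structure are
    generated by Gaussian-copula sampling from published summary statistics; an
    energy-balance body-weight model, sodium/potassium blood-pressure and
    fatty-acid lipid regressions, and recalibrated cardiovascular and diabetes
    complication risk equations drive annual state transitions; discounted
    costs and disability-adjusted life-years feed incremental
    cost-effectiveness ratios and probabilistic sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    MASS,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
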