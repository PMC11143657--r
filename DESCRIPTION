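Package: aerisk
Title: Adverse-Event Risk Estimation with Competing Events and Varying
    Follow-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and comparison of adverse-event (AE) risk in
    clinical trials with varying follow-up times, censoring, and competing
    events. Implements five estimators of the absolute AE probability
    (incidence proportion, probability-transform incidence density with
    and without competing-event hazards, one minus Kaplan-Meier, and the
    Aalen-Johansen gold standard), relative-effect estimators (risk
    ratios per basis estimator, incidence-density ratios, and cause-
    specific Cox hazard ratios with Breslow tie handling), regulatory
    categorization of absolute risks into SmPC/CIOMS frequency classes
    and of relative effects into IQWiG-style evidence classes, a
    constant-hazards competing-risks trial simulator with closed-form
    truths, and benchmarking utilities that quantify each estimator's
    bias against the Aalen-Johansen benchmark and against analytic truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cmprsk,
    jsonlite,
    knitr,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
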