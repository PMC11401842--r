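Package: aaascreen
Title: Simulation Modelling of Risk-Stratified Abdominal Aortic Aneurysm Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating polygenic-risk-score and smoking stratified
    screening strategies for abdominal aortic aneurysm (AAA). Provides a
    synthetic cohort generator with competing risks (recorded AAA versus
    non-AAA death), age time-scale Cox regression with left truncation,
    Aalen-Johansen cumulative incidence estimation, Fine-Gray subdistribution
    hazard regression, prevalence calibration against screening-programme
    data, a discrete event simulation of AAA natural history (growth, rupture,
    detection, surveillance, repair), and health-economic policy evaluation
    (discounted QALYs and costs, incremental net benefit, probabilistic
    sensitivity analysis, invitation-age optimisation and population
    aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    cmprsk
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
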