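Package: lpvalert
Title: Rule-Based Alerting Engine for Possible ARDS Without Lung-Protective
    Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An event-driven clinical decision support ("sniffer") engine that
    screens intensive-care charting streams for possible acute respiratory
    distress syndrome (ARDS) not receiving lung-protective ventilation (LPV).
    Implements trigger detection on blood-gas and chest-radiograph charting
    with inclusion and exclusion criteria, a deterministic negation-aware text
    classifier for bilateral infiltrates on radiograph reports, treatment
    adherence checks against computerized ventilation and oxygenation
    protocols (tidal volume per predicted body weight, PEEP/FiO2 grids,
    ventilator mode rules, protocol orders), an alert lifecycle with a
    per-clinician 16-hour evocation window and permanent per-patient
    suppression, and the service-outcome and accuracy statistics used to
    evaluate such tools (initial guideline nonadherence, recommendation
    adherence within a 2-hour window, alerts prevented, exact and Wald
    binomial confidence intervals, two-proportion comparison, and
    nonparametric AUROC with the Hanley-McNeil standard error). A seeded
    synthetic ICU encounter generator with planted prevalence, nonadherence
    and clinician response behaviour makes every component testable without
    patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
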