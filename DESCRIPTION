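Package: alctraj
Title: Latent Class Alcohol Consumption Trajectories and Breast Cancer Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage analysis of repeated adult alcohol-intake measurements
    and postmenopausal breast-cancer risk. Stage one fits latent class mixed
    models (finite mixtures of linear mixed models) with class-specific
    quadratic mean trajectories on the log(x+1) intake scale, multistart
    maximum likelihood, and BIC/ICL/entropy-based class selection. Stage two
    relates trajectory class to breast-cancer age at diagnosis through a
    parametric proportional-hazards model with Weibull or cubic M-spline
    baseline hazard, delayed entry, and marginalization over posterior class
    membership to correct for classification error. Includes a synthetic
    cohort generator emulating the cohort structure (retrospective intakes at
    ages 20-50 plus a baseline measure, menstrual-history fields, left
    truncated and right censored event ages) so every stage is verifiable
    against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    flexsurv,
    optparse
Config/testthat/edition: 3
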