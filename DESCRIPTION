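Package: fdgpathways
Title: FDG-PET Stratified Progression-Pathway Analysis for Cognitively
    Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies longitudinal diagnosis trajectories of baseline
    cognitively normal participants into four Alzheimer's disease
    progression pathways (stability, MCI-only decline, MCI-to-dementia
    progression, direct conversion), stratifies risk by baseline FDG-PET
    MetaROI z-scores, and quantifies pathway dynamics with discrete-time
    Markov transition matrices and sojourn times, person-time incidence
    and velocity ratios, Aalen-Johansen cumulative incidence and
    Fine-Gray subdistribution-hazard regression, multinomial pathway
    prediction with discrimination and calibration metrics, and
    Youden-optimal FDG threshold discovery.  A seeded synthetic-cohort
    generator emulating ADNI-style subject and visit tables makes the
    full pipeline testable without access to the source data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    nnet,
    jsonlite
Suggests:
    cmprsk,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
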