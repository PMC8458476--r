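Package: lynchtriage
Title: Patient-Facing Lynch Syndrome Risk Triage and Analytic-Validity Toolkit
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a patient-facing adaptation of logistic family-history
    risk scoring for Lynch syndrome: a declarative skip-logic questionnaire
    engine, bilateral (maternal/paternal) score computation with computational
    affected-side assignment, eligibility routing combining the risk score with
    a hereditary breast/ovarian cancer screen and a limited-family-history
    module, and the analytic-validity statistics used to benchmark
    patient-reported pedigrees against genetic counselor-collected gold
    standards (Lin's concordance correlation coefficient with asymptotic
    confidence intervals, power analysis, threshold misclassification). A
    seeded synthetic-cohort generator produces gold-standard and misreported
    family histories with known ground truth so the whole system is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
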