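Package: ipfvalid
Title: Validation of Case-Finding Algorithms for Idiopathic Pulmonary
    Fibrosis in Linked Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating diagnostic case-finding algorithms for
    idiopathic pulmonary fibrosis (IPF) across three linked
    electronic-healthcare sources: a primary-care event stream, hospital
    admitted-patient-care spells carrying positioned ICD-10 diagnoses, and
    death registrations distinguishing underlying from contributory causes.
    Implements eight Boolean diagnostic algorithms built from broad and
    narrow clinical code sets, hospitalisation, thoracic CT evidence and
    interstitial-lung-disease exclusion codes; computes positive predictive
    value and sensitivity against a death-certificate gold standard with
    Wilson score intervals; partitions patients into the seven exclusive
    three-source concordance regions; and reports coding-trend and cohort
    characterisation summaries. Ships a stochastic linked-cohort generator
    with a closed-form expected-PPV oracle for parameter-recovery testing,
    and a deterministic fixture builder whose marginal counts match a
    published validation study of IPF recording in English routine data.
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
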