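Package: perilink
Title: Probabilistic Mother-Infant Perinatal Record Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic linkage of birth-registration and
    hospital-admission records in perinatal health research. Provides a
    synthetic cohort generator with a configurable identifier-error and
    missingness model and full ground truth; identifier standardization
    with Soundex and NYSIIS phonetic encoding; a blocked, clue-based
    linkage engine that combines weighted field comparisons with a
    maximum-entropy (regularized logistic) match score, dual
    accept/reject probability thresholds with a clerical-review band, and
    one-to-one assignment resolution; ICD-10-AM/ACHI rule sets that
    identify infant birth admissions and maternal delivery admissions and
    derive clinical variables from diagnosis and procedure codes;
    assignment of birth records to linkage groups (complete, mothers
    only, infants only, unlinked); and reporting of linkage-rate tables,
    stratified rates, characteristic comparisons and ground-truth
    linkage-quality metrics (missed links and false positives per 1,000).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
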