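Package: crcscreen
Title: Microsimulation of Colorectal Cancer Screening with
    Indication-Specific Colonoscopy Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-event Monte Carlo microsimulation of colorectal
    cancer (CRC) screening in a birth cohort, in the CISNET family of
    adenoma-carcinoma natural-history models. Simulates adenoma onset
    under individual frailty, lesion growth, malignant transformation,
    preclinical sojourn, stage at diagnosis and CRC survival, then
    overlays screening strategies (10-yearly colonoscopy, annual faecal
    immunochemical testing, triennial multitarget stool DNA) with
    follow-up and surveillance colonoscopy scheduling. The adenoma
    sensitivity of colonoscopy can differ by exam indication (screening
    versus follow-up/surveillance) through symmetric log-odds-ratio
    scenario adjustments, and the package quantifies the consequences
    for life-years gained, CRC incidence and mortality reduction,
    adenoma miss rates and adenoma detection rates per 1000 individuals.
    Common random numbers pair every individual across strategies and
    scenarios so comparisons are within-person.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
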