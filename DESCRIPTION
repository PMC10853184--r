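Package: foldlaw
Title: Cortical Folding Morphometry and the Universal Scaling Law as a
    Neurodegeneration Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes gyrification variables (k, K, S, I, GI) from regional
    cortical morphometry (average thickness, total pial area, exposed hull
    area), fits and tests the universal cortical folding scaling law
    T^(1/2) A_T = k A_E^alpha against its theoretical slope of 1.25, removes
    linear age effects, discriminates diagnostic groups (healthy controls,
    mild cognitive impairment, Alzheimer's disease) via optimal ROC
    cut-points with stratified bootstrap, and correlates morphology with
    behavioral and cerebrospinal-fluid measures using Pearson r converted to
    Cohen's d with Bonferroni correction. Includes a calibrated synthetic
    three-group cohort generator so the full pipeline is testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
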