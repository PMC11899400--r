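Package: flavormet
Title: Untargeted Metabolomics, Flavoromics and Antioxidant Profiling for
    Harvest-Time Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for harvest-time studies of herbal
    teas that combine untargeted metabolomics, volatile flavoromics and
    antioxidant assays. Implements pooled-QC LOESS injection-order drift
    correction with RSD filtering, internal-standard relative quantification,
    log2/autoscaling preprocessing, from-scratch NIPALS PCA, PLS-DA and
    OPLS-DA with VIP scores, stratified 7-fold cross-validated Q2 and label
    permutation testing, two-step differential-metabolite screening
    (VIP > 1 and t-test p < 0.05) with upset-style cross-comparison
    integration and superclass composition, hypergeometric pathway
    over-representation, relative odor activity value (ROAV) key-odorant
    scoring with Kovats retention indices, descriptor radar grading and
    compound-descriptor networks, DPPH/ABTS IC50 and FRAP endpoint
    computation, and cross-block correlation of antioxidant, flavor and
    metabolite measurements. A seeded synthetic-data module with recorded
    ground truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
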