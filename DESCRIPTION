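Package: miwas
Title: Multi-Phenotype Association Scanning for Gut Microbiota Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population-scale comparative framework for associating gut
    microbiota composition with many binary health phenotypes (diseases and
    prescription medications). Builds marker traits from taxon count tables,
    alpha-diversity metrics and ordination axes; reduces redundancy with a
    correlation-network greedy marker selection; residualizes markers against
    technical and biological confounders with mixed models; scans all
    phenotype-by-marker pairs with logistic regression and false discovery
    rate control; clusters association profiles with cosine distances,
    complete linkage and multiscale-bootstrap cluster support; and quantifies
    disease-medication relationships with phi correlation and Jaccard overlap
    of association sets. Includes a twin-structured synthetic cohort
    simulator with planted effects so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
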