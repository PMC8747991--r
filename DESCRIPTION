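Package: ddiconcord
Title: Concordance Analysis of Drug-Drug Interaction Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the drug-drug interaction (DDI) evidence
    offered by multiple drug-information compendia. Harmonizes each
    resource's native severity and course-of-action vocabulary onto a
    common scale, scores every resource for scope (fraction of evaluated
    drug pairs with an entry), completeness (five documentation
    components summed to a 0-5 score), and majority-vote consistency of
    severity and management ratings, and quantifies inter-resource
    agreement with Fleiss' kappa (with Landis-Koch interpretation),
    exact McNemar tests on paired coverage, and exact Wilcoxon
    signed-rank tests on paired completeness scores. A seeded synthetic
    evidence-matrix generator emulates a psychotropic x COVID-19 drug
    interaction survey across six resources so the whole pipeline is
    testable without access to commercial databases.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
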