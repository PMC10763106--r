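Package: ternimmune
Title: Ternary Logic Modeling of Mucosal-Immune Steady States and
    Cytokine Cohort Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discrete ternary-logic regulatory network analysis of
    mucosal-immune signaling. Nodes take the values -1 (suppressed), 0 (normal)
    and +1 (increased) and are updated asynchronously from signed, optionally
    conditional regulatory edges; steady states are enumerated exactly by
    constraint search. Ships a curated 27-node ocular/otolaryngological
    mucosal-immune network with three reference steady states, and a
    statistical stage that measures the dissimilarity between measured plasma
    cytokine cohort profiles and each model-predicted state via Welch t-tests
    combined with Brown's method for dependent p-values, projected to two
    dimensions by stress-minimizing multidimensional scaling. Includes a
    seeded synthetic cohort generator so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
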