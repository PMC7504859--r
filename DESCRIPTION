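Package: coexrewire
Title: Differential Coexpression, Pathway Rewiring and Crosstalk Disruption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for two-condition differential-coexpression analysis
    of transcriptomes: limit-fold-change calling of differentially coexpressed
    links and genes, eigenvector-weight (GSNCA-style) pathway rewiring tests
    with hub extraction and minimum-spanning-tree wiring networks, Fisher
    combined-probability meta-analysis across datasets, hub constancy and
    retention permutation nulls, and hypergeometric pathway-crosstalk mapping
    on a scaffold of correlation-decreased links. Includes a synthetic
    two-condition expression generator with planted correlation attenuation,
    hub genes and cross-pathway couplings for validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
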