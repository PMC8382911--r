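Package: haloasr
Title: Ancestral Sequence Reconstruction and Gene-Tree Reconciliation for
    Halophilic Protein Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of the ancestral
    protein resurrection workflow used to study halophilic enzyme evolution:
    birth-death species-tree and duplication/transfer/loss (DTL) gene-history
    simulation, protein sequence evolution with gamma rate heterogeneity,
    indels and an acidic compositional bias, Felsenstein pruning likelihoods,
    site-rate estimation and fast-site/gappy-column filters, neighbor-joining
    tree inference with midpoint rooting, time-sliced DTL parsimony
    reconciliation with conditional clade probabilities, marginal
    (empirical-Bayes) ancestral sequence reconstruction with Fitch/Dollo
    ancestral-gap inference, and halophily metrics (DE/KR ratio, salt-stability
    midpoint fitting, replacement-count trajectories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
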