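Package: engraftr
Title: Reproducibility and Engraftment Fidelity Statistics for Fecal Aliquot Microbiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how faithfully a gut microbial community survives
    subsampling and transplantation. Implements rank-wise taxa recovery under a
    0.1% relative-abundance inclusion rule, percent relative abundance captured,
    OTU Venn partitions, alpha diversity (Shannon, Good's coverage) and beta
    diversity (Bray-Curtis, Jaccard, weighted and unweighted UniFrac) on
    rarefied data, PERMANOVA with strata and exhaustive enumeration, donor
    matching tests, and a serum TMAO-choline regression. Ships a synthetic-study
    generator emulating the paired straw-aliquot / germ-free-mouse engraftment
    design (8 donors, 2 aliquots and 3 recipient mice each) so the whole
    pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    phangorn,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
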