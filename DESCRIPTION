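Package: ccadigest
Title: Common Components Analysis of Anaerobic Digester 16S rRNA Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-analysis pipeline for 16S rRNA OTU count tables from
    anaerobic (co-)digestion experiments. Implements prevalence-based
    partitioning of OTUs into ubiquitous and scarce sets, total-sum and
    Pareto scaling, Common Components Analysis (a salience-weighted
    ordination in which per-variable weights are iterated to a fixed
    point for each orthogonal component), S-plot covariance-based OTU
    selection, taxonomy-cladogram loading summaries with Newick and
    GraPhlAn annotation export, per-sample richness, and Pearson
    correlation of component scores with digester performance markers.
    Includes a synthetic community generator with planted substrate
    gradients for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite,
    biomformat,
    optparse
Config/testthat/edition: 3
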