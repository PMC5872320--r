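Package: endocomm
Title: Community Diversity Analysis for Culturable Endophyte Isolation Surveys
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Infrastructure and statistics for culturable fungal endophyte
        isolation surveys: colonization rate and colonization frequency
        accounting on fragment-level isolation records, four alpha-diversity
        indices (Margalef, Brillouin, Simpson, Fisher's log-series alpha),
        Sorensen-Dice presence/absence similarity, UPGMA clustering with
        bootstrap support and Newick export, and a log-series survey
        simulator for end-to-end testing and parameter-recovery studies.
        Ships transcribed occurrence fixtures from a published ten-plant
        Artemisia thuscula survey of the Canary Islands and reproduces its
        printed diversity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
biocViews: Microbiome, Metagenomics, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
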