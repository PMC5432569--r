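Package: hypolithr
Title: T-RFLP Fingerprinting and Trophic-Structure Analysis of Hypolithic
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for terminal restriction fragment length
    polymorphism (t-RFLP) fingerprinting of desert hypolithic bacterial
    communities. Predicts terminal restriction fragment sizes by in-silico
    digestion of 16S rRNA reference amplicons, processes electropherogram
    peak tables into taxon-assigned relative-abundance profiles, computes
    the producer/consumer ratio and regresses it against macroclimate
    predictors such as the growing season, ordinates communities by
    Bray-Curtis dissimilarity with non-metric multidimensional scaling and
    group-average clustering, and implements pyrosequencing read quality
    filtering, demultiplexing, analytic rarefaction, OTU-sharing tallies and
    diazotroph screening. A synthetic-data generator produces reference
    libraries, site communities, electropherograms and reads with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
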