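Package: chromreprog
Title: Integrative Chromatin and Expression Analytics for Drug-Adaptation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise chromatin reprogramming between two
    cellular conditions from desk-scale multi-omic inputs: metabolic pathway
    activity scores from expression counts, two-group differential statistics
    with spike-in aware normalisation, histone-mark peak dynamics with
    promoter state (including bivalent) typing and active-enhancer
    definition, activity-by-contact (ABC) promoter-enhancer scoring with a
    promoter-signal-squared extension, and contact-map analytics (P(s)
    decay curves, A/B compartment eigenvectors, a seven-way compartment
    change classifier, saddle plots, insulation scores and domain
    boundaries). A seeded synthetic multi-omics generator with planted
    ground truth supports validation of every stage, and a pipeline driver
    orchestrates the stages end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
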