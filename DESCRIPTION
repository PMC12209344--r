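Package: scatdiet
Title: Diet Analysis from Scat DNA Metabarcoding Read Counts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for carnivore diet analysis from per-replicate DNA
    metabarcoding read counts of scat samples. Implements PCR-replicate
    consensus filtering with relative read abundance thresholds, read-count
    rules for identifying the defecating carnivore, frequency of occurrence
    (FOO) and weighted percent of occurrence (wPOO) diet composition,
    Pianka's dietary niche overlap with a niche-breadth-retaining
    randomization null and a scat bootstrap, and incidence-based rarefaction
    and extrapolation of diet taxonomic richness with the Chao2 estimator.
    Includes a seeded synthetic scat-read generator with known ground truth
    for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
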