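Package: dietniche
Title: Dietary Niche Analysis for Sympatric Predators from Stomach Contents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trophic ecology from stomach-content and
    prey-availability samples: abundance tables of prey counts, volumes and
    occurrence frequencies; ellipsoid prey-volume estimation; Simpson and
    Shannon diversity; Vanderploeg-Scavia electivity (E*) with chi-square
    goodness-of-fit tests and simultaneous Bonferroni confidence intervals
    (Neu's method); Pianka/MacArthur-Levins niche overlap with RA1-RA4
    randomization null models; size-class stratification and anurophagy
    summaries; and a synthetic-data generator with known ground truth for
    validating every stage. Ships the prey-count tables of a two-site field
    study of sympatric clawed frogs (Xenopus laevis and the endangered
    Xenopus gilli) in the south-western Cape as a worked case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
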