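Package: migvar
Title: Individual Variation in Migratory Behaviour from GPS Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies inter- and intra-individual variation in the
    migratory behaviour of GPS-tracked birds. Builds gridded utilization
    distributions (fixed bivariate-normal kernel and biased random bridge),
    extracts isopleth core areas and wintering areas, measures non-breeding
    distribution overlap and winter site fidelity with Bhattacharyya's
    affinity, estimates per-individual mean migration routes and route
    variation, derives migration phenology, and partitions trait variance
    into among- and within-individual components (repeatability) with
    mixed models, randomization tests and distance-constrained
    between-individual null models. Includes a synthetic track generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
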