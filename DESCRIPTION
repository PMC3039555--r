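Package: idlinkage
Title: Exact-Match Record Linkage with Identity-Collision Detection and Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step record linkage for large collections of person records
    carrying incomplete, error-prone identifiers (NHS numbers, hospital
    numbers, names and dates of birth). Records are first cleaned and joined
    by iterated exact matching on high-cardinality identifiers, including a
    constructed surname/forename/date-of-birth composite; the resulting
    clusters are then screened for identity collisions (clusters wrongly
    merging two people through a single erroneous identifier) with a logistic
    classifier over maximal within-cluster field distances, and flagged
    clusters are partitioned by deleting the identifier instance whose removal
    best restores invariant identifiers. Includes a synthetic patient-record
    generator with configurable missingness and error models, simulation
    harnesses for classifier sensitivity and splitting recovery, and a
    trigram index for fuzzy candidate search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
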