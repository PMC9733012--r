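Package: ohindex
Title: Composite One Health Indicator Frameworks with Fuzzy AHP and
    Entropy Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and weighting hierarchical composite
    health-indicator frameworks of the kind used to track joint human,
    animal and environmental (One Health) development. Provides a
    three-level indicator data model with validation and revision
    operations, subjective weighting of sibling indicator groups from
    expert pairwise-comparison questionnaires by the fuzzy analytic
    hierarchy process (row geometric means), objective weighting from
    entity-by-indicator data by the entropy weight method, integration of
    the two weight sets by squared-deviation minimisation, hierarchical
    composite scoring of entities, and seed-controlled simulators for
    expert panels and indicator data so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
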