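Package: rumselect
Title: Feature Selection by a Rough Uncertainty Metric on Fuzzy
    Neighborhood Granules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects discriminative features (e.g. feature genes) from
    continuous-valued decision tables using a rough uncertainty metric:
    fuzzy similarity relations and alpha-thresholded fuzzy neighborhood
    granules are combined with a rough-decision membership matrix in a
    conditional-entropy significance measure, which drives a greedy,
    variable-precision attribute reduction. Includes a (alpha, beta)
    parameter-grid sweep, cross-validated evaluation of selected subsets
    with a linear support vector machine and a 3-nearest-neighbour
    classifier, and a seeded synthetic decision-table generator with
    planted informative, redundant and noise attributes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    class,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
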