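Package: pcsfcm
Title: Fuzzy Cognitive Maps for Personal Construct Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a person's repertory grid and implications grid into a
    fuzzy cognitive map (FCM) of their personal construct system, simulates
    the dynamics of that system under configurable propagation and threshold
    rules, classifies constructs as congruent, discrepant or dilemmatic,
    detects cognitive conflicts in which a desired change collides with a
    construct the person is content with, and simulates what-if intervention
    scenarios (initial-state perturbations, permanent clamps and implication
    edits). Includes a healthy-habits grid template, a packaged worked
    example, a seeded random case generator, and exporters for grid files
    (CSV/JSON), iteration traces, and map digraphs (DOT, GraphML, JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
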