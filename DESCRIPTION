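Package: szind
Title: Symmetric Division Szeged Index and Related Distance-Based
    Topological Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the symmetric division Szeged index (SDZ) and a
    catalog of companion distance- and degree-based topological indices
    (Szeged, symmetric division degree, symmetric division eccentric,
    second arithmetic-geometric, reverse Szeged, reverse second Zagreb)
    for simple connected graphs.  Provides closed-form values for named
    graph families, executable verifiers for extremal bounds and
    graph-product identities, exhaustive enumeration of small trees and
    unicyclic graphs, and a QSPR workflow that regenerates the 18 octane
    isomer skeletons and correlates their indices with tabulated
    physicochemical properties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
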