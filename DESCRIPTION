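Package: jmenet
Title: Network Meta-Analysis of Resting-State Connectivity Changes in
    Juvenile Myoclonic Epilepsy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a whole-brain signed network from literature-derived
    region-pair connectivity-change records in juvenile myoclonic epilepsy
    (JME), profiles node centrality (degree and normalized betweenness),
    enumerates reduced network configurations over seeded stochastic
    node-reduction runs, extracts the high-degree core regions, and scores
    sign consistency of observed connectivity changes against white-matter
    tract-constrained sign propagation. Includes a synthetic record
    generator with planted core structure and controlled sign frustration
    so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    withr,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
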