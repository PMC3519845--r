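Package: fgnet
Title: Shortest-Path Interaction Networks, Bottleneck and Hub Ranking for
    Differential-Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds protein-interaction subnetworks around differentially
    expressed genes and ranks their essential nodes. Screens expression
    tables by fold-change and p-value thresholds, constructs shortest-path
    networks that connect seed genes to biological groups in a typed
    interactome, subtracts the subnetwork anchored on differentially
    expressed genes, scores nodes with Degree, Bottleneck (BN), Maximum
    Neighborhood Component (MNC), its density (DMNC) and the double
    screening scheme (DSS), and performs hypergeometric over-representation
    analysis against GMT annotation sets. Includes a synthetic-data
    generator with planted hubs, bottlenecks, expression effects and
    enriched terms, and a deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
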