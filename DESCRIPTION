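Package: seednet
Title: Seed-Gene Protein Interaction Network Topology and Backbone Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds an extended protein-protein interaction network from a
    disease seed-gene list and a STRING-style interaction table, extracts the
    giant component, computes degree, betweenness and closeness centralities,
    derives the high-betweenness backbone (top 5% of nodes by betweenness) and
    the subnetwork spanned by all shortest paths between seed genes, and
    validates central-node robustness with a leave-k-out seed-omission
    protocol. Includes a planted-bridge synthetic interactome generator with
    known ground truth, Pajek .net import/export, and an end-to-end pipeline
    with run manifests. The reference use case is the 69-gene essential
    hypertension candidate set centred on NOS3.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
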