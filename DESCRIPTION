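Package: plasmidrange
Title: Broad-Host-Range Plasmid Discovery via Cognate Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Screens plasmid sequence collections for complete records,
    detects cognate plasmids (near-identical sequences recovered from
    different bacterial isolates) by pairwise local alignment under explicit
    query-coverage and length-similarity criteria, groups cognates into
    network components, classifies each group's host range by the broadest
    taxonomic rank its members span, and types plasmids against
    replicon/relaxase marker references. Includes a synthetic plasmid
    population generator with planted cognate groups, taxonomy and embedded
    markers so every stage of the pipeline can be validated against a known
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
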