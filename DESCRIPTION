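Package: scaffoldmc
Title: Chromosome-Level Genome Scaffolding from Hi-C Contact Maps by MCMC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds restriction-fragment Hi-C contact maps from aligned read
    pairs, filters and recursively sum-pools them into a multi-level pyramid,
    fits a three-parameter power-law contact-decay model, and scaffolds draft
    assembly contigs into chromosome-level scaffolds by likelihood-driven
    MCMC permutation of bins. Includes deterministic post-scaffolding
    correction (consensus reorientation, run rearrangement, reinsertion of
    filtered fragments), genetic linkage-map validation and correction,
    assembly contiguity metrics, and a synthetic genome and Hi-C contact
    simulator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
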