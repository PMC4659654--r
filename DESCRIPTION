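Package: repeatome
Title: Comparative Repeatome Characterization from Low-Pass Genome Skimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based identification and quantification of repetitive DNA
    from low-coverage shotgun reads of one or many species. Reads tagged by
    species of origin are compared all-to-all with a k-mer seeded ungapped
    local aligner, similarity hits form a graph whose connected components
    are repeat clusters, and cluster read counts yield per-species repeat
    abundances (genome proportion and Mbp per monoploid genome). On top of
    the clustering layer the package provides cross-species conservation
    statistics (per-species average pairwise read similarities and per-read
    Hs/Ho intra- versus inter-specific hit-frequency ratios), an estimator
    of the ratio of solo-LTRs to full-length LTR retrotransposons (Rsf) from
    junction-spanning reads, and genome-size statistics relating repeat
    abundance to genome size variation. A multi-species repeat-genome
    simulator (LTR elements with solo-LTR formation, satellite arrays,
    dispersed repeats) generates ground-truth data for validating every
    estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
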