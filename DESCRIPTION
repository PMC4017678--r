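Package: replitimer
Title: Stochastic Simulation of DNA Replication Timing from Initiation
    Probability Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mechanistic Monte Carlo model of metazoan DNA replication
    timing. A pool of rate-limiting factors initiates replication at
    genomic sites weighted by an initiation probability landscape (IPLS),
    forks elongate bidirectionally until collision, and an asynchronous
    simulated cell population is sorted into DNA-content gates to produce
    genome-wide replication timing profiles at 500-bp resolution. Includes
    landscape builders from BED scores, transcription start sites, GC
    content, CpG observed/expected ratios and G-quadruplex motifs,
    reduced-landscape and in-silico translocation tools, simulated
    annealing optimization of flow-sorter gate boundaries, replication
    plasticity region calling against a normal null, fork-count scanning
    with a linear length scaling, and deterministic synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
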