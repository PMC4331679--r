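Package: rewirenet
Title: Inferring Signalling-Network Rewiring from Time-Course Data by
    Genetic Algorithm Search over Topologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring edge insertions and deletions ("rewiring")
    in protein signalling networks from time-course data. Candidate network
    topologies are encoded as binary chromosomes over the adjacency matrix,
    simulated as linear first-order transfer systems of ordinary
    differential equations, scored against experimental-style signalling
    and phenotype series with a dynamic time warping objective, and
    searched with a genetic algorithm. Includes consensus analysis over
    replicate runs, one-at-a-time sensitivity analysis of rate constants
    and initial concentrations, partial least squares regression with
    variable-importance-in-projection scores for validating simulated
    data, and a synthetic-data generator with planted rewiring for
    benchmarking recovery. Ships a transcription of a 22-node apoptosis
    network as the baseline topology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    withr,
    rlang,
    stats,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
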