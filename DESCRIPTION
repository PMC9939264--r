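Package: socialunits
Title: Multi-Timescale Inference of Social Units from Census and GPS Data
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <maintainer@example.org>
Description: Tools for inferring the membership of social units in
    fission-fusion, multi-level animal societies from sparse field census
    observations and GPS telemetry. Builds group-by-individual matrices and
    simple-ratio-index association networks over sliding focal windows,
    detects social units with the walktrap community algorithm either
    directly or on bootstrapped co-membership meta-networks (with a
    recursive oversize-splitting check), links per-window communities into
    persistent unit identities across time, interpolates temporarily
    missing members, and summarises unit stability (Jaccard similarity) and
    spatial cohesion (daily dyadic GPS distances). Includes a ground-truthed
    generator of synthetic multi-level societies with fission events,
    supergroup formation, and census/GPS observation processes, so that
    every stage of the pipeline can be validated without field data.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
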