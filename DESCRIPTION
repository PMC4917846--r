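Package: kcone
Title: Differential k-Cone Analysis of Metabolic Networks from
    Intracellular Metabolome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers differential enzyme activities between two cellular
    conditions from intracellular metabolome measurements and a
    mass-action metabolic network.  The space of feasible kinetic
    constants at steady state (the k-cone) is enumerated by the double
    description method, the diagonal transformation between two
    conditions' k-cones yields expected differential activities (EDAs),
    and these are tested with empirical-Bayes moderated Welch
    statistics, Bayes-bootstrap credible intervals, a flux-variability
    necessity filter for optimal growth, Jacobian-eigenvalue stability
    classification, and a heterogeneity / co-regulation screen.
    Includes a synthetic-data generator with planted regulation for
    end-to-end validation and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
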