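Package: rankmedian
Title: Rank-Distance Medians of Three Genomes and Permutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome rearrangement analysis under the rank distance,
    where genomes are encoded as symmetric permutation matrices over gene
    extremities. Implements the breakpoint-graph formulas for the rank, SCJ,
    DCJ and algebraic distances, the invariants alpha, beta and delta of the
    median-of-three problem, an exact O(n^2) median solver for the deficiency
    zero case, a compressed-sensing (per-row L1 minimization) heuristic, the
    exact polynomial-time median algorithm for orthogonal matrices based on
    rank-one orthogonal updates, projection of non-genomic medians back to
    genomes via the squared-entry probability interpretation, and a DCJ
    rearrangement simulator with the standard simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    boot,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
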