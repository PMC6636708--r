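Package: lingdiv
Title: Diversification-Rate Analysis of Dated Language Phylogenies
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how language families (or any clades on a
    time-calibrated phylogeny) expand and diversify through time.  Builds
    lineages-through-time step functions from dated trees and sums them on
    an absolute time axis, estimates overall net diversification rates
    r = ln(N)/T and doubling times ln(2)/r from extant counts and root
    ages, computes interval rates over normalized-time bins, classifies
    density dependence of diversification (negative, positive, or
    constant-rate) by regressing binned rates on lineage number, and
    fits the across-family exponential trend of rate against root age.
    Includes an exact event-driven birth-death simulator (constant,
    time-varying, and density-dependent speciation) that generates dated
    trees and synthetic family tables so the whole pipeline is testable,
    plus a command-line interface with deterministic, seeded outputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    optparse
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
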