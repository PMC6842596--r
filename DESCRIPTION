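Package: unwindr
Title: Asymmetric Base-Pair Opening and Helicase Unwindability of Nucleic Acid Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structure-based (Go-type) simulation and analysis of constant-force
    unzipping of short RNA and DNA duplexes. Builds idealized A-form and B-form
    duplex structures from sequence, constructs an all-heavy-atom structure-based
    Hamiltonian, runs Langevin dynamics under a constant end-to-end force
    (optical-tweezer mimicry), classifies base-pair-opening intermediates at the
    single-strand/double-strand junction (5'- vs 3'-dangling), removes the force
    bias by exponential reweighting, and estimates nearest-neighbor free-energy
    differences between dangling intermediates with moving-block bootstrap errors.
    From these tables it computes an "h-unwind" helix-unwindability index that
    predicts direction-dependent helicase unwinding efficiency, and it analyzes
    fluorescence unwinding time courses (amplitude, initial velocity, relative
    efficiency). Includes synthetic-data generators (junction-state Markov chains,
    biased two-state samplers, saturating-exponential kinetic traces) used as
    statistical oracles throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
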