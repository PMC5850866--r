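Package: codonmap
Title: Nonstationary Codon Models and Stochastic-Mapping Estimates of dN and dS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Branch-wise estimation of synonymous and nonsynonymous
    substitution rates (dN, dS) and their ratio under nonstationary,
    branch-heterogeneous codon models. Provides the YN98 codon model with
    F1X4/F3X4 frequency parameterizations, maximum-likelihood fitting of
    stationary and nonstationary templates on rooted trees, stochastic
    substitution mapping (endpoint-conditioned expected counts and
    reward-weighted dwell times) with neutral-model normalization, a
    nonstationary codon-sequence simulator with ground-truth event
    recording, and a driver for stationary-versus-nonstationary bias
    studies on a simulation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
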