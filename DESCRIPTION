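Package: privrep
Title: Reputation Dynamics and Evolutionary Stability of Moral Rules
    Under Private Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytical and simulation tools for the donation game with
    indirect reciprocity when reputations are privately assessed.  Encodes
    the full space of first-order moral strategies (action rules plus
    assessment rules for cooperation and defection), reduces it to its 258
    behaviourally distinct representatives, and tracks mean reputation
    (h-score) dynamics with execution and assessment errors through
    deterministic polynomial differential equations.  Provides equilibrium
    solvers for monomorphic and resident-plus-mutant populations, an
    exhaustive evolutionary-invasion (ESS) analysis over the benefit-to-cost
    range with cooperator/defector classification and invasion thresholds,
    and a compiled agent-based simulator used to validate the mean-field
    approximation strategy by strategy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
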