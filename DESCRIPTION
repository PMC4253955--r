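Package: syntorq
Title: Synergy-Constrained Decomposition of Joint Moments into Muscle
    Synergies by Direct Collocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers a shared set of non-negative muscle weightings and
    per-condition synergy control signals that, when driven through
    Hill-type muscle activation and contraction dynamics, reproduce
    experimental joint-moment time series. The decomposition is posed as
    an optimal control problem and transcribed by direct collocation with
    trapezoidal defect constraints; the resulting nonlinear program is
    solved in its reduced space by bound-constrained quasi-Newton
    iterations with exact adjoint gradients. Includes the synergy-count selection rule
    based on normalized moment-error limits, an effort-minimizing variant
    with an activation-squared penalty and its termination statistic,
    forward-dynamic consistency checks, non-negative matrix
    factorization, synergy similarity statistics, a synthetic gait-like
    plant for parameter-recovery experiments, and readers/writers for
    OpenSim storage and CSV time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
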