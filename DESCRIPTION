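Package: h4zip
Title: Kinetic Modeling of Combinatorial Histone H4 Tail Acetylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the kinetics of combinatorial acetylation of
    the histone H4 N-terminal tail (lysines K5, K8, K12, K16) by a lysine
    acetyltransferase complex. Enumerates the 16-motif acetylation state
    space and its single-site transition lattice, forward-simulates three
    competing ODE model families (mass action, Michaelis-Menten, processive
    with an optional within-array hand-off), calibrates them to targeted-MS
    motif time courses by multi-start maximum likelihood, ranks them by AIC,
    quantifies parameter uncertainty by posterior ensemble sampling with
    bounded uniform priors, and generates counterfactual predictions such as
    disabling all reactions at K16 (the K16R scenario). A synthetic-data
    module emulates the targeted-MS measurement structure (MS1 peak areas,
    light enzymatic vs heavy chemical acetyl bookkeeping, 0.003 percent
    detection limit) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
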