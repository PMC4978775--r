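Package: lckautoreg
Title: Kinetic Modeling of LCK Autoregulation on Reconstituted Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Rule-based construction of the LCK/CSK trans-phosphorylation
    reaction network, stiff ODE simulation of membrane-reconstitution
    experiments, synthetic phospho-time-course generation, two-stage
    ensemble parameter estimation (particle swarm global search on a hybrid
    weighted-least-squares objective followed by bounded Levenberg-Marquardt
    refinement), ensemble selection and clustering, and eFAST variance-based
    global sensitivity analysis of the 38 kinetic parameters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    cluster,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
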