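Package: vaultsim
Title: Finite-Element Simulation and Parametric Analysis of Spring-Assisted
    Posterior Vault Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates spring-assisted posterior vault expansion (SAPVE), a
    craniofacial procedure used to increase intracranial volume in children
    with syndromic craniosynostosis. Generates simplified calvarium shell
    models with anatomical landmarks, realizes a parametrized osteotomy and
    spring-distractor placement on the mesh, solves quasi-static viscoelastic
    shell finite-element expansion driven by pre-compressed torsional springs,
    extracts intracranial volume as the 3D convex hull of the deformed model,
    and quantifies the local sensitivity of the post-expansion volume to the
    surgical parameters via space-filling designs of experiments and quadratic
    response surfaces, with per-procedure cohort statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
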