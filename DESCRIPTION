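Package: aggdiffenv
Title: Aggregation-Diffusion Dynamics in Heterogeneous Environments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying one-dimensional aggregation-diffusion
    equations in a heterogeneous environment. Provides closed-form
    steady-state families for quadratic diffusion with either a Laplace
    interaction kernel or its fourth-order local approximation, constrained
    single-aggregation candidate profiles on a clumped resource landscape,
    evaluation and rapid minimisation of the associated energy functionals
    over the aggregation half-width, and positivity-preserving finite-volume
    time integration of the nonlocal, fourth-order local, and
    linear-diffusion model variants, with mass, energy, and positivity
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
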