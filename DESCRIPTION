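Package: thermocrm
Title: Thermodynamic Microbial Consumer-Resource Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates microbial community assembly with a thermodynamic
    consumer-resource model in which species harvest energy from substitutable
    resources, leak a fraction of it back to the environment as metabolic
    byproducts (cross-feeding), and compete in a chemostat supplied with a
    single external resource. Provides samplers for random regional species
    pools and Dirichlet metabolic matrices, stiff ODE integration to steady
    state with extinction handling, community observables (energy budgets,
    flux networks and their topology, Simpson flux diversity, resource
    susceptibilities, rank-abundance), macroecological pattern analysis
    (NODF nestedness with null-model z-scores, PCA beta-diversity), and
    reproducible phase-diagram, niche-overlap, beta-diversity and system-size
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    withr
Config/testthat/edition: 3
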