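Package: fesfold
Title: Free Energy Landscapes and Folding Pathways by Force Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs high-dimensional free energy surfaces over
    collective variables by force matching: mean forces estimated at
    K-means-selected centers are fit with a symmetry-respecting neural
    network whose negative gradient reproduces the forces.  Includes
    collective variables for nucleosome arrays (inter-nucleosome
    distances, fraction of native contacts, radius of gyration),
    analytic benchmark potentials with overdamped Langevin samplers,
    metadynamics combined with temperature-accelerated dynamics for
    conformational exploration, umbrella sampling with WHAM for
    one-dimensional cross-validation, marginal free energy profiles,
    and the finite-temperature string method for most-probable
    transition pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    bio3d,
    tools,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
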