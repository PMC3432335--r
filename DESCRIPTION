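Package: swarmreg
Title: Hybrid Particle Swarm Optimization for Multimodal 3D Rigid Image
    Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A hybrid particle swarm optimizer (HPSO) that combines the
    classic inertia-weighted particle swarm update with two genetic-algorithm
    ingredients, island-style subpopulations and arithmetic crossover of the
    two best subpopulation leaders, together with the rigid 3D multimodal
    image-registration pipeline it was designed for: a mutual-information
    similarity computed from a joint intensity histogram, a six-parameter
    rigid transform, and trilinear backward-warp resampling of medical
    volumes. Includes a benchmark harness (sphere, Rosenbrock, Rastrigin and
    Griewank test functions with a seeded multi-run protocol), a synthetic
    multimodal phantom generator for end-to-end parameter-recovery
    experiments, landmark-based error evaluation, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
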