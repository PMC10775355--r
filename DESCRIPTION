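Package: vertexclosure
Title: Vertex-Model Mechanics of the Amnioserosa During Dorsal Closure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of epithelial tissue mechanics during
    Drosophila dorsal closure with an extended two-dimensional vertex model.
    The amnioserosa is represented as a periodic, confluent polygonal tiling
    whose energy penalizes deviations of cell areas and perimeters from
    preferred values; closure is driven by quasistatic uniaxial compression
    combined with a linear active shrinkage of polydisperse preferred cell
    perimeters and random cell ingression. The package provides the tissue
    geometry and T1/T2 topology moves, analytic forces with a FIRE energy
    minimizer, the closure protocol and its isotropic-deformation control,
    cell-shape and junction-tension observables, a tension-network rigidity
    (percolation) analysis with phase-diagram construction, experiment-side
    computations (closure staging, junction straightness, laser-ablation
    recoil fitting, straightness-recoil crossover), and synthetic-data
    generators that emulate tracked-cell tables and ablation traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
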