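Package: hcpesp
Title: Electrostatic Surface Potential with Hierarchical Charge Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the electrostatic surface potential (ESP) of biomolecules
    under the analytic linearized Poisson-Boltzmann (ALPB) model, using either an
    exact all-atom summation or the hierarchical charge partitioning (HCP)
    multi-scale approximation, in which the charge distributions of distant
    structural components (residues, polymer strands, the whole complex) are
    replaced by small sets of representative point charges selected per surface
    vertex by distance thresholds. Includes a PQR and surface-vertex file reader
    and writer, a synthetic structure and vertex generator for controlled
    experiments, accuracy (relative RMSE) and work (kernel-evaluation count)
    comparison utilities, a single- versus double-precision study, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
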