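Package: osseoFEM
Title: Finite-Element Stress Analysis of Platform-Switched Dental Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Comparative finite-element evaluation of threaded, platform-switched
    dental implants placed in a synthetic maxillary premolar bone segment.
    Provides parametric implant and bone geometry, synthetic Hounsfield-unit
    volumes with threshold segmentation, graded quadratic tetrahedral meshing,
    a linear isotropic elasticity solver with Zienkiewicz-Zhu error recovery
    and mesh-convergence certification, and principal-stress-based peri-implant
    overloading risk statistics over cortical and trabecular control volumes.
    Includes study drivers for implant-design sweeps, in-bone positioning depth
    comparisons, and marginal bone-loss sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, Rcpp, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'osseoFEM-package.R'
    'classes.R'
    'implant-geometry.R'
    'bone-geometry.R'
    'catalogue.R'
    'meshing.R'
    'fem.R'
    'mesh-io.R'
    'recovery.R'
    'scenario-io.R'
    'stress-risk.R'
    'study.R'
    'synthetic-ct.R'
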