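Package: ctFFR
Title: CT-Derived Fractional Flow Reserve on Synthetic Coronary Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for computing fractional flow reserve (FFR)
    from volumetric angiographic images: synthetic coronary-tree phantom
    generation with ground truth, lumen segmentation by fast marching with
    colliding-fronts initialization and level-set refinement, surface
    extraction, centerline and stenosis quantification, physiological boundary
    conditions from myocardial mass with allometric scaling and Murray's law,
    steady incompressible Newtonian finite-volume flow solvers (axisymmetric
    SIMPLE and a reduced-order network model), FFR extraction with the 0.80
    ischemia threshold, and a diagnostic-concordance stage (2x2 metrics with
    exact confidence intervals, ROC/AUC, Pearson correlation, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
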