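Package: fluororeg
Title: Marker-Based 3D2D Rigid Registration of Vertebrae from Two-View
    Fluoroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rigid 3D2D registration of individual vertebrae from a
    pre-existing CT-like attenuation volume to a pair of angulated
    fluoroscopic views, as used in navigated spine surgery. Implements
    ray-driven digitally reconstructed radiograph (DRR) formation, a
    gradient-difference similarity measure with intensity-scale
    estimation, CMA-ES pose optimization in two stages (coarse
    two-vertebra single-view, then per-vertebra two-view), relative
    C-arm pose estimation from radiopaque skin-marker spheres via
    Umeyama alignment, a procedural spine-phantom generator with
    ground-truth per-vertebra poses, and a target registration error
    (TRE) evaluation harness with rotation-angle-difference (RAD) sweep
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
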