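Package: kneeforge
Title: Automated Patient-Specific Knee Implant Planning at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully automated planning workflow for total knee
    arthroplasty: slice-wise bone segmentation post-processing (morphological
    filtering, marker-based watershed separation, isosurface meshing with
    Taubin smoothing), augmented statistical shape models (generalized
    Procrustes alignment, PCA with landmark channels, Davies quality metrics),
    three-stage robust fitting of shape models to partial proximal/distal bone
    extremities, anatomical landmark propagation with osteophyte-risk-weighted
    refinement, morphometric parameter extraction, and parametric medial-pivot
    implant design scored by bone-implant over/under-hang. A synthetic
    femur/tibia generator with exact ground truth (correspondence, landmarks,
    label masks) makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    RNifti,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
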