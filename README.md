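# kneeforge

Automated patient-specific knee implant planning at desk scale, in R.

Total knee arthroplasty (TKA) replaces the femorotibial joint surfaces with
implants. Custom implants that match the patient's anatomy reduce overhang
and under-coverage — leading causes of residual pain — but designing them is
traditionally a slow, manual engineering loop. kneeforge implements the full
automated planning chain for people who study or prototype such workflows:

1. **Segmentation** of CT-like volumes: a pluggable slice-predictor contract
   (default: intensity threshold) followed by morphological filtering,
   marker-based watershed separation of femur and tibia, tetrahedral
   isosurface meshing and Taubin smoothing.
2. **Statistical shape models** (SSMs): generalized Procrustes alignment,
   PCA of corresponded surfaces *augmented with anatomical landmark
   channels*, truncation at 99% variance, and the Davies quality triad
   (compactness / generality / specificity).
3. **Partial fitting**: full bones are reconstructed from the segmented
   proximal/distal extremities in three stages — bounding-box scaling,
   globally initialized rigid/similarity ICP, and a ridge-regularized,
   osteophyte-robust mode fit. The model

   `x(b) = mean + sum_i b_i * sqrt(lambda_i) * mode_i`

   is fitted by minimizing `||S(b) - closest-surface-targets||^2 + ridge * ||b||^2`
   with trimming of outlier matches, coefficients `b` in standard-deviation
   units.
4. **Morphometrics**: landmark propagation through the fitted model,
   osteophyte-risk-weighted refinement to the segmented surface, mechanical
   axes, AP/ML sizes, condylar line and sulcus angle.
5. **Implant design**: parametric medial-pivot profiles — pivot radius from
   the AP size, tibial baseplate contouring with posterior retreat, insert
   with low-congruence lateral surface — scored by bone-implant
   over/under-hang (RMSE and Hausdorff distance) outside clinically
   motivated ignore zones.

A synthetic femur/tibia generator with exact ground truth (correspondence,
landmarks, label masks, osteophytes, partial fields of view, pseudo-CT)
replaces clinical data, so every stage is buildable and testable offline.

## Worked example

```r
library(kneeforge)

# a synthetic training population with exact correspondence
tpl <- make_template("femur")
pop <- sample_population(tpl, n = 20, k_latent = 6, sd = 2, seed = 7)
model <- truncate_model(build_model(corresponded_set(pop), bone_kind = "femur"), 0.99)
length(model$variances)
#> [1] 4                      # modes retaining >= 99% of variance

# reconstruct a held-out bone from its cropped extremities
ho <- sample_population(tpl, 2, 6, 2, seed = 99)[[1]]
cr <- crop_extremities(ho$mesh, 0.3, 0.3)
fit <- fit_partial(model, partial_observation(cr$proximal, cr$distal, "femur"))
surface_distance(fit$reconstructed, ho$mesh)$rmse
#> [1] 0.142                  # mm, symmetric surface RMSE vs ground truth

landmark_error(propagate_landmarks(fit), ho$landmarks)
#> [1] 0.55                   # mm, mean over the 12 femoral landmarks

# design both implants for a synthetic knee and score coverage
ks <- knee_scene(make_template("femur"), make_template("tibia"))
d <- design_knee_implants(ks$femur$landmarks, ks$tibia$landmarks,
                          ks$femur$mesh, ks$tibia$mesh)
c(d$femoral$medial_radius, d$coverage$femur$rmse, d$coverage$tibia$rmse)
#> [1] 22.573  0.250  0.508   # pivot radius (mm); coverage RMSE (mm) per bone
```

The reconstruction RMSE is the symmetric vertex-to-surface error against the
uncropped ground truth; the coverage RMSEs measure how closely each implant
contour follows the resected bone contour outside the ignore zones (the
tibial posterior retreat is excluded by design).

A thin command-line front end over the same functions lives at
`inst/cli/kneeforge.R` (`synth`, `segment`, `build-ssm`, `fit`, `evaluate`).

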