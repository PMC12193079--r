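---
title: "Methods: automated knee implant planning at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated knee implant planning at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

kneeforge is a desk-scale implementation of a fully automated planning
pipeline for patient-specific total knee arthroplasty (TKA): CT-like volumes
are segmented into femur and tibia, full bones are reconstructed from the
segmented joint extremities with augmented statistical shape models (SSMs),
anatomical landmarks and morphometric parameters are extracted, and a
parametric medial-pivot implant is designed and scored by bone-implant
over/under-hang. This vignette explains the models, the tunable parameters,
the synthetic data the pipeline is validated on, and the design choices made
where several defensible options existed.

## The synthetic bone generator

Clinical CT datasets cannot ship with a package, so every stage is exercised
against a generator with exact ground truth.

**Templates.** `make_template()` builds a right femur (380 mm) or tibia
(360 mm) as a closed tube of revolution whose radius field blends a tapered
shaft with joint-end primitives: posterior condylar bumps, a trochlear
groove, a femoral head and greater trochanter; plateau lobes, a tibial
tuberosity and a medial malleolus. The coordinate frame is fixed: +z
proximal, +y anterior, +x lateral for a right bone; left bones are obtained
by mirroring x. Every named landmark is attached to a mesh vertex, so it
lies exactly on the surface and is carried exactly by any vertex deformation
- generator correspondence and landmark ground truth are exact by
construction, not approximated. The default template has about 2,500
vertices and 5,000 faces, which keeps a principal component analysis and the
iterative closest point (ICP) loops comfortable on a single CPU while
leaving the condylar geometry well resolved; coarser templates (the test
suite uses ~700 vertices) only change resolution, not topology.

**Population variation.** `sample_population()` deforms the template by a
linear combination of `k_latent` fixed smooth basis fields - low-order
polynomial vector fields of normalized coordinates (bends, transverse
inflation, taper, bows, mid-shaft bulge and shifts), Gram-Schmidt
orthonormalized so one coefficient unit produces 1 mm RMS per-vertex
displacement. Coefficients are i.i.d. normal with standard deviation `sd`
(default 2, i.e. ±4 mm typical surface excursions - a plausible
inter-subject range for knee morphology; the clinical variance magnitude is
not documented, so this is a configured choice, not a calibration). A
recorded isotropic scale jitter, uniform on [0.92, 1.08], emulates patient
size. Two classes of fields are deliberately absent from the catalogue:
pure lengthening, torsion and axial shear are dominantly *tangential* on a
tubular surface - they re-parameterize the surface without changing the
shape set, which makes their coefficients unrecoverable from any
surface-distance measurement and would make "ground-truth latent recovery"
an ill-posed target. Length-to-width variation is still present through the
transverse fields combined with the similarity scale.

**Pathology and acquisitions.** `add_osteophytes()` adds 3-8 Gaussian
radial bumps (radius 4-10 mm, height up to 6 x severity mm) at joint-margin
vertices along smoothed vertex normals; landmark coordinates are *not*
displaced - osteophytes are exactly what the downstream fitting must ignore.
`crop_extremities()` keeps the proximal/distal fractions of a bone with open
crop boundaries, emulating hip/knee/ankle acquisitions.
`rasterize_ct()` voxelizes bones by z-column parity, assigns 700 HU to a
2-voxel cortical shell, 300 HU to the interior and 40 HU to background, and
adds Gaussian noise; the paired label mask is noise-free ground truth.
What the generator does **not** emulate: trabecular texture, cartilage,
partial-volume blur, metal artifacts, bone-on-bone contact in collapsed
joints, or a patella. Passing tests therefore demonstrate correctness of
the algorithms under controlled conditions, not clinical performance.

## Segmentation

The learned 2D segmentation models used clinically are replaced by a
*slice predictor contract*: any function mapping an intensity slice to
foreground probabilities in [0, 1] plugs in; `default_slice_predictor()` is
a threshold (default 200 HU, midway between background and the cortical
shell). The bespoke logic is in the post-processing, which is what the
package actually validates: per-slice binarization, 3x3 morphological
opening and closing, removal of 2D components below 30 mm^2, stacking, and
retention of the two largest 6-connected 3D components. When a knee volume
yields a single fused component, it is split by marker-based watershed on
the inverted interior chamfer distance transform; markers are the two
largest distance maxima at least 10 mm apart (ties broken by distance, then
voxel index), and label 1 (femur) goes to the more proximal component.
Meshes come from a tetrahedral isosurface extraction (a watertight variant
of marching cubes: each cube is split into six tetrahedra sharing a
diagonal, removing the ambiguous configurations that can puncture a
classic implementation), followed by Taubin lambda/mu smoothing
(lambda = 0.5, mu = -0.53, 10 iterations), which smooths voxel staircase
without volume shrinkage.

## Augmented statistical shape models

A corresponded set stacks, per member, the 3V vertex coordinates and the 3L
landmark coordinates scaled by the landmark weight `w_L` (default 1) into
one shape vector - this is the "augmentation": landmarks live in the same
linear model as the surface, so fitting the surface also positions the
landmarks. Members are aligned to a generalized Procrustes reference
(similarity transforms, mean-displacement tolerance 1e-6 mm, at most 50
iterations; the mean's centroid size is pinned to the average input size so
millimetres stay physical). PCA is computed by singular value decomposition
of the centered data matrix; all `min(P-1, 3(V+L))` modes are stored and
`truncate_model()` keeps the smallest mode count reaching 99% of variance.
Mode coefficients are expressed in standard-deviation units (scaled by
sqrt(lambda)), so a ridge penalty on them is a Mahalanobis prior.
For targets without generator correspondence, `correspond()` provides
non-rigid registration: similarity initialization, then ten rounds of
closest-point matching and a Laplacian-regularized displacement solve with
stiffness annealed geometrically from 10 to 0.1.

Model quality uses the standard triad: compactness (cumulative variance
fraction), generality (symmetric surface RMSE of unseen members after
orthogonal projection onto the first N modes) and specificity (minimum
symmetric surface RMSE of randomly synthesized shapes to any training
member). The model container on disk is JSON with named fields (mean,
modes, variances, topology, landmark names, weight, provenance).

## Fitting partial observations

Reconstruction from two cropped extremities runs in three stages.

1. **Bounding-box scale.** Per-axis ratios between data and model-mean
   extents, measured by an identical procedure on both sides: longitudinal
   extent along the axis through the two piece centroids; transverse
   extents from plane-projected principal directions of each piece,
   averaged over the two pieces and clamped to [0.8, 1.25] of the
   longitudinal ratio. Averaging and clamping matter: a single joint end
   with unusual width must not dictate a global anisotropic scale the
   deformation modes cannot undo.
2. **Rigid/similarity registration.** The scaled mean's end regions are
   registered by ICP with a globally initialized candidate sweep: both
   longitudinal orientations x eight azimuths about the axis. Candidates
   are scored *symmetrically* (forward residual plus data-to-model
   residual) because a wrong azimuth can hug the data one way while leaving
   condylar lobes unexplained; the best candidates of *each* orientation
   are refined. For unusual anatomy the upside-down or rotated pose can
   genuinely out-score the true one on any rigid criterion, so every raw
   candidate is additionally screened by a short deformation fit - a wrong
   basin must distort the modes to chase the data, which its residual
   exposes sharply - and the best-screened candidates are carried forward.
   Refinement ends with a point-to-plane Gauss-Newton
   polish (closest-point ICP stalls in the shaft's sliding directions) and
   a longitudinal anchor (the two pieces span the bone's full length, so
   the z placement is determined; plain ICP may slide along the
   near-cylindrical shaft).
3. **Robust mode fitting.** Model vertices inside the observed longitudinal
   windows (inset 3 mm at the crop-plane side only - the anatomical end
   caps carry the length information) are matched to closest points on the
   partial surfaces; the ridge-regularized least squares for the
   coefficients alternates with a similarity-pose refresh. Robustness to
   osteophytes combines a hard match cap (5 mm) with outlier-aware
   trimming: once the warm phase has settled, matches far above the typical
   residual level (3x the 90th percentile, at least 1 mm) are discarded up
   to the `trim_frac` budget and the exclusion set is frozen by vertex id,
   which keeps the alternation from oscillating and never sacrifices
   accurate-but-informative regions on clean bone. Up to two warm
   restarts re-run the loop from the converged pose and coefficients when
   the residual stays above 0.3 mm; the iteration cap is 40 with a 1e-4
   coefficient tolerance, so typical cases stop long before it.
   Finally the fit is *canonicalized*: the converged reconstruction is
   re-expressed as a pure similarity pose times mode coefficients, so the
   reported `b` is comparable across fits and free of the working
   anisotropic initialization scale. All candidate poses are deformed and
   the lowest-residual fit wins.

At low osteophyte severity the ridge prior and the match cap already
neutralize the bumps and trimming is a no-op by construction (nothing
exceeds the trimming floor); its measurable benefit appears once bump
heights enter the 1-5 mm band, which is where the robustness property is
tested.

## Landmarks and morphometrics

Landmarks propagate through the fitted model (they are part of the shape
vector) and are then adjusted toward the segmented mesh by
`p' = p + w * clamp(proj(p) - p, max_shift)` with `max_shift` 5 mm. The
per-name risk weights encode osteophyte risk: 0.2 for the epicondyles and
tibial wear points (joint-margin, osteophyte-prone), 0.8 elsewhere -
clinical workflows weight this adjustment by osteophyte risk but published
values are not available, so these are configured defaults. Secondary parameters are built covariantly
from landmarks: the femoral mechanical axis runs from the femoral head
center to the femoral knee center (defined here as the top-notch point
projected onto the plane through the mid-distal-condyle point orthogonal to
the head-to-mid-condyle direction); the tibial knee center is the midpoint
of the condyle centers; AP size projects the sizing point against the mean
posterior condyle along the anatomical AP direction; the anatomical frame
is (lateral, anterior, proximal) built from the mechanical axis and the
projected transepicondylar line. All lengths and angles are rigid-motion
invariant by construction.

## Implant design and coverage

The design is 2.5D: planar section contours plus parametric profiles, not a
solid CAD model. Resections use surgeon-style defaults (distal cut 9 mm,
posterior cut 8 mm, tibial cut 8 mm below the higher wear point with 3
degrees of posterior slope). Contours are extracted by mesh-plane
intersection, keeping the largest closed loop, expressed in a plane frame
whose second axis is the anatomical anterior direction, canonically
oriented counter-clockwise with arc length zero on the anterior ray - this
canonical parameterization is what makes arc-length ignore zones comparable
between bone and implant contours. The medial-pivot radius is a linear law
(0.33 x AP size) standing in for the unpublished clinical sizing rule; the
condylar arcs are positioned tangent to both resection planes. The tibial
baseplate is the resected contour offset inward by 0.5 mm with a 3 mm
posterior retreat (smooth shoulders) and a fillet pass; a collapsing offset
is reported as a design failure rather than raised, mirroring the workflow
bookkeeping of invalid designs. The femoral footprint insets the bone
contour by 0.25 mm, so it cannot overhang by construction. The insert adds
a 0.5 mm clearance to the medial socket and a low-congruence lateral
surface (factor 2). Coverage is the unsigned bone-implant contour distance
outside the ignore zones (tibial posterior sector 0.35-0.65 of arc length;
femoral sectors centered on the intercondylar-notch and trochlear-groove
projections).

## Numerical choices and limitations

Closest-point queries are exact point-to-triangle distances accelerated by
a uniform grid; ties go to the lowest triangle index. Voxelization jitters
ray origins by a deterministic sub-voxel offset to avoid edge-exact
intersections. Watershed and trimming tie-breaks are by value then index,
so every operation is a pure function of its inputs and seed. The
acceptance experiments use 5 knee subjects at 1 mm spacing with 30 HU
noise, 20 training and 10 held-out bones, and 10 design subjects - sizes at
which every stage's behaviour is already stable while the whole suite runs
on one CPU in minutes.

Known limitations: the slice predictor is a threshold, so segmentation
results speak to the post-processing, not to learned models; the generator's
variation basis is smooth and low-dimensional, so generality/specificity
numbers are not comparable to clinical SSMs; knee-only acquisitions cannot
determine bone length (the workflow requires hip, knee and ankle volumes);
and the implant stage designs profiles and contours, not manufacturable
solids.
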