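---
title: "Reconstruction of the proximal tibia from biplanar radiographs and automated osteotomy planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction of the proximal tibia from biplanar radiographs and automated osteotomy planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Medial opening-wedge high tibial osteotomy (HTO) realigns a varus knee by
cutting the proximal tibia and opening a wedge until the leg's mechanical
axis — the frontal-plane polyline through the hip, knee and ankle joint
centers (HJC, KJC, AJC) — reaches a target. Three-dimensional planning of
the cut, the correction angle and the fixation plate normally requires a CT
scan; calibrated biplanar standing radiographs (EOS-style: simultaneous
frontal and sagittal views with a vertically translated horizontal fan
beam) are cheaper, lower-dose, and weight-bearing. `osteoplan` implements a
complete desk-scale pipeline from such image pairs to an optimized surgical
plan:

1. a **synthetic phantom cohort** with known deformity replaces a patient
   CT cohort, so every stage is trainable and testable without data;
2. a **DRR simulator** renders calibrated biplanar radiographs from the
   phantoms, including the clinical pose in which the right leg stands
   slightly anterior (a 40–60 mm shift plus a 10–20° sagittal rotation);
3. three **convolutional networks** — sagittal leg separation, heatmap
   landmark localization, and 2D–3D reconstruction of the proximal
   tibia — are trained on the simulated studies;
4. **measurement**: landmarks are triangulated to 3D, the reconstruction is
   surfaced, and the mechanical axis (MA) and tibial slope (TS) are read
   off; and
5. a **multi-objective genetic algorithm** searches the twelve-parameter
   osteotomy plan space.

## The phantom and what it does (not) emulate

Each leg is an analytic scene: a femoral shaft cylinder with a femoral-head
sphere, a tibial shaft cylinder capped by an elliptic plateau slab, and a
soft-tissue envelope, in a right-handed patient frame (+X medial→lateral
toward the right, +Y posterior→anterior, +Z inferior→superior,
millimeters). The two controlled deformity parameters are the frontal-plane
varus angle of the tibial axis (the constructed MA) and the posterior
inclination of the plateau normal (the constructed TS). Because the scene
is analytic, ground truth — joint centers, the proximal-tibia label on any
grid, MA and TS — comes from the construction, never from re-measuring
voxels, and the right-leg augmentation transforms the primitives rigidly
before re-voxelizing, so a zero transform is bit-identical.

Cohort variability draws varus and slope uniformly from 2–12° per leg
(HTO candidates are varus), leg length from N(360, 12) mm and tibial shaft
radius from N(13, 0.8) mm, both legs sharing size draws. These are desk
choices for a plausibly varied surgical population at a leg length that
fits a 448 mm detector field.

Phantom bones are continuous from hip to ankle; clinical dose-sparing CT
protocols often image only the joints and skip the shafts, a gap the
phantom does not emulate. Beyond that, the phantom deliberately omits: cortical/trabecular texture (intensities
are piecewise constant — sufficient for line-integral DRRs),
osteoarthritic plateau irregularity, the fibula and patella (off by
default; the reconstruction target is only the proximal tibia), scanner
effects (scatter, beam hardening, noise) and pose variability beyond the
right-leg shift. Passing tests therefore demonstrate that the *pipeline
machinery* is correct and learnable, not that the networks transfer to
real radiographs — domain realism is exactly what the DRR-versus-real gap
leaves open.

## Projection geometry

Both modes share the vertical axis: a 3D point maps to the same detector
row in the frontal and sagittal view, because the emitter translates
vertically. `parallel` mode (the default) integrates along −Y (frontal) or
−X (sagittal) and makes triangulation closed-form: X from the frontal
column, Y from the sagittal column, Z as the mean of the two row heights.
`fan` mode places a per-row point source 1300 mm before the axis and the
detector 300 mm behind it (configurable plumbing; the exact vendor geometry
is not public), magnifying only the horizontal axis; triangulation is then
the least-squares midpoint of the two back-projected rays, with the ray gap
reported as a residual. Images are min–max normalized per image and the
range is kept in metadata.

## The three networks and their losses

No deep-learning framework is available to this package's target
environment, so it ships a small native network core (Rcpp/Armadillo):
3×3(×3) same-padding convolutions via im2col (2D) or offset-grouped GEMM
(3D), 2× max pooling, nearest-neighbor upsampling, ReLU, He-normal
initialization, Adam, and hand-written backpropagation for the three fixed
topologies. Gradients of every layer and loss are verified against finite
differences in the test suite.

* **Separation** — one 2D encoder, two decoders with skip connections
  (right and left leg), sigmoid outputs. Targets are the single-leg
  sagittal DRRs after the contrast transform
  `f(x) = 1/(1 + exp(−(x − 0.45)/0.12))`, which suppresses soft tissue so
  the network separates bone rather than silhouette. The loss is
  `(MSE + (1 − GC))/2` where GC is the gradient correlation: the mean of
  the normalized cross-correlations of the horizontal and vertical image
  gradients (central differences, zero at borders; zero-variance inputs
  define GC = 0 with a warning). GC is a similarity, so it enters the
  minimized loss as `1 − GC`; its role is sharpening the separated leg
  outlines.
* **Landmark localization** — a 2D U-net regressing one unit-peak Gaussian
  heatmap per landmark (σ = 5 px by default) under binary cross-entropy
  (predictions clipped at 1e−7). The frontal network emits 6 channels
  (HJC, KJC, AJC per side), the sagittal network 3, run on each separated
  image. Because the two legs look locally identical in the frontal view
  and convolutions are translation-equivariant, the landmark networks
  receive two extra input channels holding normalized horizontal and
  vertical coordinate ramps; without them the side-specific channels
  cannot converge. Peaks are decoded by argmax refined with a 7×7
  center-of-mass window, ties toward the smaller (v, u).
* **2D–3D reconstruction** — the frontal and sagittal knee crops pass
  through two separate 2D branches for two levels; each branch's S/4 × S/4
  feature map is replicated S/4 times along its missing axis, the two
  volumes are averaged per voxel into a fused 3D feature map, and the rest
  of the encoder and the whole decoder are 3D, with skip connections at
  the fused levels only, ending in a background/tibia softmax. The loss
  sums a per-class soft-Dice term and the mean cross-entropy. At the
  reference scale (512 px inputs) the fusion cube is 128³; the desk preset
  uses 128 px inputs and a 32³ cube.

Reference hyperparameters are kept in the `full` preset: learning rates
0.001/0.0001/0.00005, epochs 20/20/30, batch sizes 16/1/1 for
separation/landmarks/reconstruction. The `desk` preset — used by the test
suite — trains 8/14(+8)/3 epochs at larger learning rates
(1.5e−3/2e−3/1e−3) with 8/8/6 base channels on 128 px images, sizes chosen
so a 40-phantom experiment (train 29 / val 7 / test 4 patients) runs in
minutes on one CPU while still reaching held-out Dice ≈ 0.89 and ≈ 1.6 px
mean landmark error.

### Reconstruction inputs and the separation ablation

The reconstruction network sees knee-centered crops: a 32 px (112 mm)
window around the knee, cut from the frontal image and from the separated
(or, for the ablation, unseparated) sagittal image at the shared vertical
rows, upsampled ×4 to the 128 px network input so the two 2D levels land
back on the crop grid. The crop center is the detected (or ground-truth)
knee position. Ground-truth targets are sampled analytically from the
phantom scene on the 32³ crop grid: tibia voxels within 90 mm of the knee
center (the desk proximal-tibia span; 120 mm at full scale). The ablation
harness trains a second reconstruction network on unseparated sagittal
crops — at desk scale the contralateral shaft genuinely overlaps the
window after the clinical shift — and reports mean Dice per side plus the
relative improvement `(full − ablated)/ablated × 100`.

## Measurement conventions

* **MA** is reported as deviation from collinearity in the frontal plane:
  0° = straight leg, positive = varus of the measured side (the side flag
  flips the sign for the left leg). The measured angle between the
  hip–knee and knee–ankle lines is 180° − MA.
* **TS** is the angle between the plateau-plane normal and the knee–ankle
  line, both projected to the sagittal plane; positive = posterior slope.
* The **plateau plane** is a total-least-squares fit to mesh vertices
  within 8 mm of the most superior vertex whose outward normals lie within
  30° of +Z. Band, cone and the RMS fit residual are exposed because
  articular-plane fitting is the known weak point of slope measurement
  from two projections; downstream code can gate on the residual.
* **Isosurfaces** come from a signed exact Euclidean distance transform of
  the binary volume, lightly Gaussian-smoothed (σ = 1 voxel; skipped
  automatically if smoothing would erase the foreground) and polygonized
  by tetrahedral decomposition (6 tetrahedra per cell). This yields
  watertight, consistently oriented meshes whose surface areas match
  analytic solids to ~1%, which the voxel staircase would not.
* **Dice** is `2|A∩B|/(|A|+|B|)` with empty∪empty = 1; the **mean surface
  distance** is the asymmetric mean of prediction-vertex to closest point
  on the truth surface (point-to-triangle, via a uniform spatial index
  verified against a brute-force scan).

## Planning

A plan has 12 scalars: hinge-axis frontal position (ML, SI), axis
direction (azimuth from +Y, elevation), opening angle, cutting-plane
inclination about the axis, plate position (3) and plate orientation (3).
The package's convention — the literature leaves the moving fragment
unstated — is a medial opening wedge in which the fragment distal to the
cutting plane (plus the ankle center) rotates rigidly about the hinge
axis, with the sign chosen per side so a positive opening angle reduces
varus. Achieved MA is re-measured from the corrected joint centers;
achieved TS from the (unmoved) plateau plane and the corrected knee–ankle
line. Note that the MA change equals the opening angle exactly only when
the hinge sits at the knee's frontal position; a distal hinge shortens the
lever arm, which the optimizer compensates.

The three fitness components are |MA − Φ_MA|, |TS − Φ_TS| and the mean
plate-to-bone distance over ≥ 20 plate sample points (same closest-point
machinery as the surface metric); infeasible plans (hinge outside the
bone) evaluate to +∞. Feasibility rules — lateral hinge bridge ≥ 10 mm,
cut ≥ 15 mm below the plateau, plate on the medial cortex — are a
simplified, fully configurable stand-in for the clinical constraint
catalogue and are reported rule by rule.

The search is NSGA-II (population 100, generations 100 by default;
simulated binary crossover η = 15, polynomial mutation η = 20, rate 1/12)
over per-case bounds anchored at the knee center; the hinge-bridge and
cut-depth rules are enforced as hard constraints during the search. From
the final non-dominated front the selected plan minimizes the MA
deviation, ties — within a 0.25° band, since exact ties never occur
between continuous objectives — broken by TS deviation and then by plate
gap. This is an explicit convention; any front member is defensible.

## Numerical choices and degenerate inputs

Probability clipping 1e−7 in all log terms; GC defined 0 on zero-variance
gradients; empty projections return zero images instead of dividing by a
zero range; all-zero heatmap channels decode to an NA sentinel;
marching-cubes errors on empty (or full) volumes; the plane fit errors
below 10 candidate vertices; triangulation propagates missing landmarks as
NA. All randomness flows from per-stage seeds derived from one global
seed; training, cohort generation and the GA are bit-reproducible given
the seed in a single-threaded session.

## Known limitations

The networks are trained and evaluated on phantom DRRs only; TS accuracy
degrades with plateau irregularity that the phantom does not model; the
fan-beam distances are plumbing defaults, not vendor calibration; the
plate is an abstract rigid patch, not vendor geometry; and the desk preset
trades capacity for CPU minutes — the `full` preset restores the
reference scale but is not intended to run inside the test suite.
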