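---
title: "Motion-informed femoral attachment localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-informed femoral attachment localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpflopt)
```

## The problem

In medial patellofemoral ligament reconstruction (MPFLR), the femoral
tunnel position largely determines how the graft's length changes as the
knee flexes. The standard radiographic landmark, the Schöttle point
(S-point), is defined on static imaging and ignores how a particular
patient's patella actually travels. Given time-resolved CT of active
flexion — 20–30 frames, each providing a femoral surface and a patellar
point cloud — this package finds an *individualized* femoral attachment
(I-point) whose straight-line distance to the patellar articular centroid
(C-point) stays as constant as possible over the motion, while remaining
surgically interpretable: on the femoral surface, 5–15 mm from the S-point.

## Model

Write $P_{C_i}$ for the C-point of frame $i$ ($i = 1, \dots, N$) in a
femur-fixed coordinate system, and $P_I$ for the candidate attachment. The
fitted quantity minimizes the variance of the modeled ligament length,

$$
f(P_I) \;=\; \frac{1}{N}\sum_{i=1}^{N}
  \Bigl(\lVert P_I - P_{C_i}\rVert - \bar{L}(P_I)\Bigr)^2,
\qquad
\bar{L}(P_I) = \frac{1}{N}\sum_{i=1}^N \lVert P_I - P_{C_i}\rVert,
$$

subject to three inequality constraints $g(P_I) \le 0$:

$$
g_1 = r_{\min} - \lVert P_I - P_S\rVert,\quad
g_2 = \lVert P_I - P_S\rVert - r_{\max},\quad
g_3 = d_{\mathrm{surf}}(P_I) - \varepsilon_{\mathrm{surf}},
$$

with $r_{\min} = 5$ mm, $r_{\max} = 15$ mm around the S-point $P_S$, and
$d_{\mathrm{surf}}$ the Euclidean distance to the triangulated femoral
surface. $\sqrt{f}$ is the length standard deviation in mm and is reported
alongside $f$. The on-surface condition is an equality in spirit; it is
relaxed to a band of half-width $\varepsilon_{\mathrm{surf}}$ (default
0.1 mm) during iterations so that the constraint set has an interior, and
the final iterate is projected exactly onto the surface.

The straight-line length is a deliberate simplification: no graft wrapping,
soft-tissue contact, or loading is modeled, so a small $\sqrt{f}$ is a
geometric statement about isometry of the attachment pair, not a
biomechanical validation.

### Anatomical frame

All analysis coordinates live in a femur-centered frame built from three
landmarks: origin at the midpoint of the medial and lateral condyle points
(MFC, LFC); X along LFC→MFC (medial–lateral), mirrored for left knees so +X
is always medial and left/right cohorts pool; Z the component of the shaft
axis point (RA) orthogonal to X, pointing proximally (proximal–distal); and
Y = Z × X (anterior–posterior), giving a right-handed orthonormal basis.
Two conventions here were genuinely open and are package decisions:

* RA is consumed as a *point* on the reconstructed shaft axis; only its
  offset from the origin matters.
* The landmark triple (MFC, LFC, RA) spans the X–Z plane under this
  construction. The alternative reading — that the landmark plane is X–Y —
  is incompatible with Z being proximal–distal when RA sits on the shaft
  axis, and the proximal–distal labeling is what the cohort statistics are
  expressed in, so it wins.

### Patellar trajectory

The C-point is the arithmetic centroid of the patellar cloud (optionally of
a labeled articular subset). Per-frame centroids, expressed in the femoral
frame, are fitted by independent least-squares polynomials of degree 3 per
coordinate — enough to follow a smooth 0–90° path with 20–30 frames without
oscillation. Two uses are kept strictly apart:

* the optimizer targets the **raw** per-frame centroids (the objective sums
  over frames);
* the **fitted curve** only serves evaluation on the 0°, 10°, …, 90° angle
  grid and filling of empty angle bins.

When per-frame flexion angles are supplied (and non-decreasing) they are
the fit parameter; otherwise the normalized frame index is used, and
angles are assigned afterward by normalized arc length along the fitted
curve scaled to 0–90°. That fallback is a package convention — the source
imaging protocol does not define a flexion angle computation, and no tibia
is modeled — so angle-binned outputs under the fallback are comparable
within, but not necessarily across, datasets. The fit's `rms_residual` is
the per-coordinate RMS residual in mm.

### The SQP solver

The constrained program is solved by sequential quadratic programming in
the three coordinates of $P_I$:

* **QP subproblem.** At iterate $P_I^k$, minimize
  $\tfrac12 \Delta^\top H_k \Delta + \nabla f^\top \Delta$ subject to the
  linearized constraints $g_i + \nabla g_i^\top \Delta \le 0$ (solved with
  `quadprog`); the subproblem's multipliers are the new $\lambda$.
* **Hessian.** $H_k$ is a damped BFGS approximation of the Lagrangian
  Hessian (Powell damping, started at the identity), which keeps it
  positive definite.
* **Globalization.** Steps are accepted by backtracking on an
  $\ell_1$ merit function $f + \mu \sum_i \max(0, g_i)$ with the penalty
  $\mu$ kept above the largest multiplier; step length is capped at a
  quarter of the annulus width plus 1 mm.
* **Gradients.** $\nabla f$ is analytic. $\nabla g_3$ is the unit vector
  away from the closest surface point (analytic within each
  closest-triangle region); central differences ($h = 10^{-5}$ mm) take
  over on the surface itself, where that direction is undefined.
* **Convergence.** Stop when the objective change falls below
  $10^{-10}$ mm² *and* the KKT residual (stationarity, feasibility,
  complementarity) below $10^{-6}$, or after 200 iterations.
* **Multi-start.** The objective is nonconvex on a curved surface, so the
  solver starts from the `n_starts` (default 10) annulus vertices with the
  lowest objective plus the surface projection of the S-point when
  feasible. Feasible seeds remain candidates, so the returned optimum can
  never be worse than the best annulus vertex — which is also the
  exhaustive-oracle dominance property the tests assert. The incumbent is
  then polished by up to three restarts with a fresh Hessian; this guards
  against premature line-search exits with a stale BFGS model.
* **Determinism.** Ties are broken by distance to the S-point, then
  lexicographically; the whole pipeline is deterministic given its inputs.

The independent check on all of this is `brute_force_ipoint()`, an
exhaustive evaluation of $f$ at every surface vertex inside the annulus.

### Surfaces

Triangle meshes pass through unchanged apart from removal of triangles with
area below $10^{-6}$ mm² (they destabilize barycentric projection). Raw
point clouds are reconstructed as the boundary of the alpha complex of the
3D Delaunay tetrahedralization (hand-built Bowyer–Watson incremental
construction): tetrahedra with circumradius ≤ α are solid; faces of exactly
one solid tetrahedron form the regular boundary; and Delaunay faces with no
solid neighbor are kept as singular surface faces when their own
circumradius is ≤ α and their diametral ball is empty (Gabriel condition) —
the regime that reconstructs thin, hollow surface samples, where every
tetrahedron spans the cavity. The default α is twice the median
nearest-neighbor spacing, which adapts to sampling density without
per-subject tuning. A deterministic relative jitter of $10^{-7}$ of the
bounding-box diagonal breaks cospherical degeneracies in the incircumsphere
predicate; it affects only the combinatorics, never the output coordinates.

### Length profiles

For an attachment $P$, per-frame lengths $L_i = \lVert P - P_{C_i}\rVert$
are normalized as $\mathrm{MPFL\%}_i = 100\,(L_i - L_{\mathrm{ref}}) /
L_{\mathrm{ref}}$. The reference length is not prescribed by the source
protocol; the package default is the per-subject mean length across frames
(under which the per-frame MPFL% averages to exactly zero), with
length-at-angle available (`reference = list(at_angle = 30)`) for
sensitivity analyses. Positive MPFL% is elongation. Frames are binned at
0°, 10°, …, 90° by the half-open rule $[\theta-5, \theta+5)$ with the end
bins clamped to [0, 90]; empty bins are filled from the fitted trajectory.

### Cohort statistics

Paired S/I coordinates across knees are compared with:

* **PERMANOVA**: pseudo-$F = \mathrm{SS_{between}}/(\mathrm{SS_{within}} /
  (n - 2))$ on raw Euclidean mm distances (no standardization — the
  coordinates share units). The permutation $p$ shuffles group labels,
  includes the observed statistic in numerator and denominator
  ($p = (1 + \#\{F^\ast \ge F\}) / (1 + n_{\mathrm{perm}})$, the
  bias-avoiding convention; the source does not state its own), and is
  reproducible given a seed. Small problems can be enumerated exhaustively.
* **Axis partitioning**: the share of the squared mean separation per axis,
  $\Delta_a^2 / \sum_b \Delta_b^2$ — for equal group sizes, each axis'
  share of the between-group sum of squares. Applied to the published
  cohort means it reproduces the reported ~95% proximal–distal share; this
  formula was chosen because it reproduces those printed shares and is
  documented as reverse-engineered.
* **Paired Wilcoxon signed-rank** per axis and per angle bin: zeros
  dropped, midranks for ties, exact null distribution for $n \le 25$ by
  convolution over the $2^n$ sign assignments (identical to full
  enumeration, verified against it), normal approximation with continuity
  and tie corrections above. No multiplicity correction across the ten
  angle bins by default, matching per-angle reporting practice; Holm can be
  applied by the caller.
* **MDS/KDE**: classical (Torgerson) scaling and Gaussian kernel densities
  (Silverman bandwidth) for visualization; Shapiro–Wilk (the standard
  routine) only gates reporting — the pipeline is nonparametric throughout.

One reporting caveat: the published coordinate table's per-axis "Cov"
column is not self-explanatory (its values are inconsistent with the
printed confidence intervals under any reading we tried), so the package
reports plain per-axis variances instead and makes no attempt to match that
column.

## The synthetic-data generator

Because the source imaging data is private, every stage is validated on
synthetic knees built to the published scale:

* **Femur**: two condylar spheres (radius ~22 mm) bridged by a shaft
  cylinder, triangulated at ~900 vertices by default; MFC/LFC are the exact
  extreme medial/lateral points (so their distance is the intercondylar
  width, 81 mm by default, matching reported anatomy), RA lies on the
  shaft axis, and the S-point is a designated medial-condyle surface point.
* **Motion**: a rigid, exactly zero-mean ellipsoidal patellar cloud is
  swept along a non-planar arc so that its centroid keeps distance
  $L^\ast + \varepsilon_i$, $\varepsilon_i \sim N(0, \sigma)$, from a
  planted surface point $P^\ast$ 5–15 mm from the S-point
  ($L^\ast = 55$ mm by default, the published mean ligament length). With
  $\sigma = 0$ the planted point is the global optimum with objective
  exactly zero. The arc is deliberately non-planar: points equidistant from
  a planar arc form a whole line, which would make the optimum
  unidentifiable.
* **Cohorts**: paired S/I rows with S drawn around the published mean
  (39.15, −1.29, 9.32) mm and I = S + δ + noise, δ defaulting to the
  published separation (−0.38, −0.19, 1.88) mm — i.e. a ~1.9 mm proximal
  shift; per-axis spreads are set from the published confidence intervals.

What passing on these fixtures shows — and what it does not: recovery of a
planted optimum on a smooth two-sphere femur demonstrates the optimizer and
the geometric plumbing, not robustness to segmentation noise, trochlear
morphology, articular-surface delineation, or landmark identification
error, none of which the generator emulates. Statistical calibration runs
(type-I error, planted shifts) validate the test machinery at the cohort
sizes used, not any clinical claim.

All generator randomness flows from explicit integer seeds; identical seeds
give bit-identical outputs. Per-simulation seeds inside larger experiments
are drawn from one master stream.

## Problem sizes and runtime choices

The validation experiments use 50 random geometries for planted-optimum
recovery and oracle dominance (~900-vertex meshes, 25 frames), 100 fits for
the length-SD dominance property, 500 null simulations at $n = 20/20$ with
199 permutations for PERMANOVA calibration, and 100 random samples for the
signed-rank enumeration check; the full suite completes in a few minutes on
one CPU. These sizes were chosen so each rate estimate has a standard error
well inside its acceptance band.

## Known limitations

* Straight-line ligament model; no wrapping, routing, or loading.
* Frames must already share one scanner space; no frame-to-frame
  registration is performed.
* The flexion-angle fallback (arc length) is a convention, not a
  measurement.
* The alpha-shape reconstruction assumes reasonably uniform sampling; very
  anisotropic clouds may need a hand-chosen α.
* Synthetic femurs are geometric idealizations (see above).
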