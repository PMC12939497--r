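# mpflopt

Motion-informed, patient-specific femoral attachment localization for
medial patellofemoral ligament (MPFL) reconstruction.

## What problem this solves

The femoral tunnel position in MPFL reconstruction drives how the graft
lengthens and shortens as the knee flexes. The conventional landmark — the
radiographic Schöttle point (S-point) — is defined on static imaging and
cannot reflect an individual patient's patellar tracking. Given
time-resolved CT of active knee flexion (20–30 frames, each with a femoral
surface and a patellar point cloud) plus anatomical landmarks, `mpflopt`
fits an **individualized femoral attachment (I-point)**: the point on the
femoral surface, 5–15 mm from the S-point, whose straight-line distance to
the patellar articular centroid (C-point) varies least over the motion.

The fitted quantity is the variance of the modeled ligament length over the
N motion frames,

    f(P_I) = (1/N) Σ_i ( ‖P_I − P_Ci‖ − L̄(P_I) )²,

minimized subject to g(P_I) ≤ 0 with

    g1 = r_min − ‖P_I − P_S‖,   g2 = ‖P_I − P_S‖ − r_max,
    g3 = dist_surface(P_I) − ε_surf,

solved by sequential quadratic programming (damped BFGS, ℓ1-merit line
search, multi-start from the best annulus vertices) with an exhaustive
vertex scan as an independent oracle. Around the fit, the package provides
the femur-centered anatomical frame (X medial–lateral, Y
anterior–posterior, Z proximal–distal), patellar trajectory fitting,
normalized length-change (MPFL%) profiles per 10° flexion bin, and cohort
statistics (PERMANOVA with permutation p, per-axis variance partitioning,
exact paired Wilcoxon signed-rank, classical MDS, kernel densities). A
synthetic-knee simulator with planted isometric optima makes every stage
testable without clinical data.

Audience: musculoskeletal imaging / orthopedic biomechanics researchers and
computational surgery-planning developers.

## Worked example

Simulate a knee at anatomical scale (81 mm intercondylar width, ~55 mm
ligament length, 25 frames over 0–90°, 0.3 mm radial noise) and fit the
I-point:

```r
library(mpflopt)

spec <- synthetic_spec(sigma = 0.3)
fem  <- make_femur(spec)
seq1 <- make_motion(spec, fem, seed = 42)
fit  <- fit_ipoint(seq1, fem$landmarks)
print(fit)
#> Motion-informed femoral attachment fit - subject 'synthetic' (right)
#>   I-point (local mm): 23.97, -3.36, 20.90
#>   S-point (local mm): 30.56, -7.69, 16.46
#>   |I - S| = 9.04 mm
#>   length SD: I 0.371 mm vs S 1.058 mm
```

The I-point lies 9.04 mm from the S-point (inside the 5–15 mm annulus) and
cuts the ligament-length standard deviation from 1.06 mm (S-point) to
0.37 mm — the level of the injected noise, i.e. essentially all systematic
length change has been optimized away. `summary()` adds the per-angle
profile:

```r
summary(fit)
#>   mean length: I 55.37 mm, S 60.38 mm
#>   length SD:   I 0.371 mm, S 1.058 mm
#>   MPFL% range: I [-1.38, 1.23], S [-4.07, 2.14]
#>   MPFL% per 10 deg bin:
#>  angle  S_pct  I_pct
#>      0 -3.903 -0.292
#>     10 -2.664 -0.113
#>     ...
#>     90  1.626  0.788
```

MPFL% is the percent deviation of the frame-wise length from the
per-subject mean length; the S-point column shows the familiar pattern of
shortening near extension and elongation in flexion, while the I-point
stays near zero. `coef(fit)` returns the I-point coordinates,
`predict(fit)` evaluates lengths on an angle grid, `plot(fit)` draws both
profiles, and `write_results(fit, dir)` exports JSON/CSV reports.

Cohort-level comparison of paired S/I coordinates:

```r
co <- make_cohort(seed = 7)              # 58 synthetic knees
sm <- cohort_summary(co, n_perm = 999, seed = 7)
#> pseudo-F 2.599, p 0.062; proximal-distal (Z) share 94.3%
```

A command-line interface wrapping the same functions lives at
`inst/cli/mpflopt.R` (subcommands `simulate`, `frame`, `optimize`,
`profile`, `stats`, `run-all`).

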