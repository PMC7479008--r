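---
title: "Polar outline curves for craniosynostosis phenotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar outline curves for craniosynostosis phenotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniocurve)
```

## The model

The package describes a cranial vault cross-section as a function
$r(\theta)$: the distance from the section's area centroid to its boundary,
sampled at every integer degree and divided by the mean radius. The
construction is anchored entirely in external anatomy:

* the cutting plane is defined by left/right exocanthion and one porion and
  offset 40 mm superiorly, a height at which the cross-section clears the
  orbits;
* $\theta = 0$ is the occipital intersection of the perpendicular bisector
  of the exocanthion–exocanthion segment, and $\theta$ increases past the
  patient's right side first, so curves from different subjects are in
  angular register;
* division by the mean radius removes overall size, hence age.

On such a curve the five common single-suture phenotypes separate through a
handful of named quantities (forehead peak $F$ at angle $XF$, occiput $O$,
side troughs $R$, $L$ at $XR$, $XL$; the $F-0.1$ crossing angles $XFR$,
$XFL$): elongation shows in $(F+O)/(R+L)$, frontal pointedness or flattening
in the forehead width $(XFL - XFR)/(F - 0.1)$, and unilateral coronal
synostosis in the deviation of $XF$ from 180°.

### Assumptions

* The outline is a simple closed polygon, star-shaped as seen from its
  centroid. When a ray crosses the boundary more than once the outermost
  intersection is used and a warning is raised — the curve is then no longer
  a faithful boundary description and should be inspected.
* The centroid lies strictly inside the polygon (violated only by extreme,
  non-cranial shapes; reported as an error).
* The three plane landmarks are non-collinear, and the superior side is
  known (by default the mesh centroid serves as the superior hint).

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| plane offset (`height`) | 40 | mm | analysis height above the base plane; "the 4 cm plane" |
| `side_of_porion` | left | – | right only for left-sided anterior plagiocephaly; always an explicit input, never auto-detected |
| angular resolution (`n_samples`) | 360 | deg⁻¹ | all named features are defined on the 1° grid |
| forehead search window | [90°, 270°] | deg | enforces the occiput–right–forehead–left ordering of the curve |
| occiput window | 0° ± 45° | deg | window for the occipital peak $O$ |
| peak drop (`drop`) | 0.1 | relative radius | level below $F$ defining the forehead-width crossings |
| centering window (`peak_window`) | ±12 | deg | 3.5 % of 360° ≈ 12.6; boundaries inclusive |
| `t_scapho` | 1.40 | – | length/width ratio calling scaphocephaly |
| `t_trigono` | 66 | deg per relative radius | forehead width below which trigonocephaly is considered |
| `t_brachy` | 110 | deg per relative radius | forehead width above which brachycephaly is considered |
| `asym_window` | [0.7, 1.6] | – | asymmetry ratios compatible with a centered forehead |
| `brachy_fo_tol` | 0.03 | relative radius | maximal forehead–occiput height difference for brachycephaly |

The classifier thresholds are heuristics interpolated from the published
per-phenotype feature regimes of small clinical groups (five subjects per
phenotype): control length/width ≈ 1.31 vs scaphocephaly ≈ 1.49;
forehead width ≈ 48 (trigonocephaly), ≈ 79 (control), ≈ 123
(brachycephaly). They are deliberately exposed in `cranio_config()` and
should be re-estimated when larger reference cohorts are available;
classification accuracy is asserted only on phantoms.

### Design choices where the construction was open

* **Derived-variable sign.** The printed formula sheet lists the
  occiput/forehead-versus-sides differences as $O - (R/2 - L/2)$, but the
  published worked value for scaphocephaly (1.24 − 0.81 = 0.43) is
  consistent only with the mean of sides, $O - (R/2 + L/2)$. The package
  computes the mean-of-sides form by default and keeps the printed variant
  behind `strict_table1 = TRUE`. Likewise the published "48.5 % longer than
  wide" does not follow from the printed group means
  ((1.16 + 1.24)/(0.81 + 0.81) = 1.481); such rounding-dependent values are
  noted here rather than asserted in tests.
* **Anterior direction.** The in-plane anterior axis is the projection of
  (exocanthion midpoint − porion used); the posterior of the two bisector
  intersections is the one with a negative anterior component, the farther
  one from the ex midpoint when several qualify.
* **Start construction plane.** The start point is built in the 4 cm plane
  from exocanthions projected along the plane normal (`start_plane =
  "slice"`); projecting in the base plane is available as a flag and is
  identical whenever projection is along the shared normal.
* **Ties.** Equal extrema break toward the canonical angles (180° for the
  forehead, 90°/270° for the troughs, 0° for the occiput), so a perfectly
  flat plateau yields its most central angle.
* **Normalization.** The arithmetic mean of the 360 sampled radii is the
  normalizer; 1.0 therefore *is* the mean value by construction.
  Perimeter- or area-based normalizations were rejected as they break that
  reading.
* **Post hoc chain.** Games-Howell p-values and Bonferroni-adjusted values
  (m = number of pairs) are reported side by side, and significance is
  flagged on the adjusted value — the conservative reading of applying both.
* **Levene's test** uses mean centering (the classical form), not the
  median-centered Brown–Forsythe variant.
* **ICC aggregation.** Landmark reliability is reported per coordinate axis
  and additionally on the 3-D Euclidean deviation from the per-subject
  landmark mean, since coordinates are recorded per axis but reliability of
  the *point* is what matters; an axis with no variance at all has an
  undefined ICC and is reported as `NA`.

## Numerical choices

* Mesh–plane intersection perturbs exactly-on-plane vertices by 10⁻⁹ mm,
  avoiding degenerate coplanar triangles; segments are chained into loops
  by the mesh edge each endpoint lies on, which is exact (no coordinate
  rounding), and the largest-area loop is kept so slices that also cut
  ears or noise blobs still return the vault outline.
* Ray–boundary intersection is exact per segment (2 × 2 linear solve in
  cross-product form); no vertex interpolation of the polygon is involved.
* The bisector–outline intersection counts sign changes of the boundary
  against the line, with on-line vertices assigned to the positive side, so
  a vertex lying exactly on the bisector yields exactly one crossing.
* Crossings of the $F - 0.1$ level are linearly interpolated between
  integer degrees; fractional crossing angles are intended.
* A ray grazing a polygon vertex produces two nearly identical hits; only
  crossings more than 10⁻⁶ mm apart count toward the non-star-shape
  warning.
* Degenerate inputs raise typed conditions (collinear landmarks, empty
  slice, open contour, flat curve, peak too flat, undefined ICC, singleton
  group, ...), each with a distinct command-line exit code.

## The phantom generator

Real CT data cannot ship with the package, so study conditions are emulated
by seeded superellipsoid head phantoms (`phantom_spec()`,
`generate_phantom()`, `generate_cohort()`). The cross-section radius at
azimuth $\phi$ (0 = anterior) is a superellipse with anterior-posterior and
lateral semi-axes, deformed by

* *angular warps* that widen or sharpen the frontal and occipital peaks
  while keeping both apices on the midline (flat broad forehead for
  brachycephaly; pointed keel forehead for trigonocephaly),
* Gaussian angular *bosses* at the forehead and occiput (the frontal boss
  center is deviated ±34° for anterior plagiocephaly, together with a
  one-sided frontal flattening),
* a random order-2/3 harmonic *wobble* emulating normal between-subject
  shape variation, and
* spatially smoothed vertex-wise Gaussian radial *noise* emulating surface
  extraction error (smoothed because extraction error is smooth at the
  millimetre scale; unsmoothed noise makes a polygonized outline locally
  non-star-shaped at amplitudes real surfaces never show).

Vertically the section is scaled along an ellipsoidal profile into a
closed, watertight mesh; exocanthion and porion landmarks are placed
parametrically on the noise-free surface in the $z = 0$ plane, so the
landmark-defined base plane is exactly $z = 0$ and the analysis plane
$z = 40$ mm. Noise-free shape parameters were set during design to the
published per-phenotype regimes (length/width 1.31 control / 1.49
scaphocephaly / 1.28 trigonocephaly / 1.21 brachycephaly; forehead widths
47 / 78 / 124; plagiocephalic peak angles 155° / 205°) and are not fitted
to any test outcome. Controls receive wider between-subject jitter than the
synostotic groups, emulating the reported finding that normal shape
variation is wide while synostosis constrains shape — which is what makes
the control group's per-degree curve range the largest under matched noise.

**What phantoms do not emulate.** Real cranial outlines are not generated
by a low-order radial model: they carry local bone detail, soft-tissue
asymmetries, and landmark placement error (phantom landmarks are exact).
Phantom cohorts are cleaner than patients — per-degree ranges
(≈ 0.03–0.05) are smaller than the published patient values (0.07–0.12),
and classification accuracy on phantoms (typically ≈ 95 % for five subjects
per group, occasionally dipping just below 90 % at unlucky seeds) says
nothing about clinical accuracy. Equally, the published patient-data
results — ICCs of 0.994–1.000 and the group p-values — require the original
CT and rater data and are *not* reproduced here; the test suite covers them
with property-based analogues (jittered-rater ICC > 0.99, control range >
synostotic range, type-I error at nominal level).

## Problem sizes

The shipped tests and the acceptance script run at deliberately small
scale: phantom meshes of 192 × 64 azimuthal/polar divisions (≈ 24k
triangles), cohorts of five subjects per phenotype (30 meshes), 1000
replicates for the type-I simulation and ICC noise table, and 300
replicates for the post hoc power check. These sizes keep every property
comfortably measurable; all of them scale up linearly if sharper Monte
Carlo error is wanted.

## Known limitations

* The forehead width divides degrees by a relative radius, an intentionally
  unit-odd quantity inherited from the printed formula sheet; it is kept as
  printed for comparability.
* The outermost-intersection rule makes non-star-shaped outlines yield a
  defined but lossy curve; severe shape anomalies outside the five
  phenotypes may need a different boundary parameterization.
* The classifier is a small ordered rule list, not a learned model; its
  thresholds encode five-subject group ranges and a mirrored pair, and the
  trigonocephaly/plagiocephaly disambiguation leans on the 180° ± 12° rule
  alone when the asymmetry ratio is inconclusive.
* `side_of_porion` is diagnosis-dependent in the source protocol, which is
  circular at classification time; in practice both porions are near-mirror
  images and the left-porion default changes phantom classifications only
  marginally (the cohort accuracy figures use the default throughout).
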