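---
title: "Measuring the 3D curvature of the femoral canal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the 3D curvature of the femoral canal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The femoral shaft bows anteriorly, and to a lesser and more variable
extent medially or laterally. `femcurve` models the medullary-canal
centerline as an arc of a single circle in 3D space. Three quantities
describe that circle in an anatomically standardized frame:

- the **radius of femoral curvature (RFC)**, the circle's radius in mm —
  large for straight femurs (the observed anatomical range spans roughly
  500 to 2000 mm);
- the **banking angle** beta, the inclination of the plane containing the
  circle relative to the coronal plane, measured so that the bow apex
  direction "opens" toward the medial side: beta = 90 deg is a pure
  anterior bow, beta < 90 deg an anteromedial apex, beta > 90 deg an
  anterolateral apex;
- the **isthmus diameter**, the smallest maximum-inscribed-circle diameter
  of the canal cross-sections, which sizes an intramedullary nail.

The single-circle model is an approximation: real canals are not exactly
circular arcs, and the fit residual (`fem_circle$rmse`, in mm) quantifies
how far a given canal departs from it. The model's value is that it makes
the relationship between the 3D bow and its planar projections exact: an
arc of radius R at banking beta projects onto the sagittal plane as an
ellipse with apex radius of curvature `R / sin(beta)` and onto the coronal
plane with apex radius `R / |cos(beta)|` (`apex_projected_radius()`). The
coronal radius therefore *increases* as beta rises toward 90 deg and
*decreases* beyond it — a non-monotonicity that explains why planar
coronal measurements correlate poorly with the 3D bow, while sagittal ones
correlate well whenever beta stays near 90 deg.

Because the banking angle is defined through the apex direction rather
than as a plane dihedral, angles beta and 180 - beta are distinguishable;
a dihedral alone could not tell an anteromedial from an anterolateral
apex. This is an interpretation: descriptions of the angle as "opening
toward the medial side" motivate it, and all values above 90 deg reported
by the package rely on it.

## The standardized frame

All angles are meaningless without a reproducible anatomical frame. The
package emulates an osteometric board: the coronal plane is y = 0 (bone in
y >= 0, +y anterior), the axial plane is z = 0 (bone in z >= 0, +z
proximal), and the medial direction is +x for left femurs and -x for right
ones. Two deterministic "settling" stages replace a physics simulation:

1. `settle_on_plane()` computes the convex hull of the bone, keeps the
   facets that are statically stable (the center of mass, projected along
   the facet normal, falls inside the facet), and rests the bone on the
   stable facet with the largest contact triangle among those facing
   within 60 deg of the gravity direction. The area preference matters:
   tilted roll-contact facets (e.g. two posterior landmarks plus the side
   of the femoral head) can face gravity more directly than the true
   posterior three-point support, but always with a smaller triangle.
2. `slide_to_axial()` keeps the coronal contact and rotates about y until
   the bone rests on a stable edge of its (x, z) convex hull whose two
   support vertices are at least 10 mm apart (two condyles, not a point).
   Among the stable candidates it chooses the edge that leaves the center
   of mass highest: a femur is heavier toward the head, so this uniquely
   selects "distal condyles down, head up" from any starting rotation.
   The contact pair is placed at z = 0 with its midpoint at x = 0, which
   pins the last free translation and makes the final vertex coordinates
   pose-invariant.

The gravity direction for stage 1 defaults to the *bow-derived* estimate
`-bow_apex_direction()`: coarse cross-section centroids of the central 70%
of the bone are fitted for their bow, and the apex of that bow points
anterior. This makes the full standardization invariant to the initial
rigid pose of the input, which a fixed "-y" gravity cannot achieve — a
femur dropped on its side genuinely rests on its side. Users settling
non-anatomical shapes can pass `down` explicitly.

Femoral length is the axial (z) extent of the standardized bone — the
bounding-box property a CAD package reports — rather than a 3D
point-to-point distance; for anatomical bows the two differ by well under
0.1%.

## Tunable parameters

| Parameter | Where | Default | Units | Why |
|---|---|---|---|---|
| `n_slices` | `extract_centerline()` | 96 | – | ~3 mm station spacing on a 300 mm canal; doubling changes the fitted RFC by < 0.2% |
| `trim_fraction` | `extract_centerline()` | 0.10 | – | the centroid estimates near the canal openings are unreliable; 10% per end removes them without touching the isthmus |
| `tol` | `max_inscribed_circle()` | 0.005 | mm | refines the inscribed diameter to ~0.01 mm |
| `p_enter`, `p_remove` | `stepwise_regression()` | 0.05, 0.10 | – | the conventional clinical-statistics thresholds |
| `mc_reps` | `ks_normality()` | 10000 | – | Monte-Carlo Lilliefors null; the table depends only on n and is cached |
| `n_samples` | `check_clearance()` | 20000 | – | doubling changes `min_clearance` by < 0.01 mm on the synthetic fixtures |
| `tube_diameter` | `build_torus()` | – | mm | use the *measured* (inscribed-circle) isthmus diameter so the verdict is consistent with the meshed canal wall |

Angles are degrees at every API boundary and radians internally; all
lengths are mm.

## The synthetic-femur generator

`make_femur_meshes()` builds watertight cortex and canal meshes directly
in the standardized frame, so the ground-truth standardization transform
is the identity and every downstream stage can be tested against exact
truth:

- the canal is a tube swept along an analytic circular arc (default
  radius 971.44 mm, banking 93.48 deg — the cohort means of the population
  the defaults emulate), with a quadratic radius profile whose single
  interior minimum is the isthmus (default diameter 10.5 mm at arc
  fraction 0.55);
- the default arc span is 16 deg, chosen so that the canal (lesser
  trochanter to condylar flare) occupies roughly two thirds of a 428 mm
  femur at the default radius;
- the cortex is the canal tube thickened by `cortex_thickness` (default
  5 mm), extended distally with a 1.5x condylar flare and proximally
  through a tapering neck into a 21 mm-radius spherical head whose most
  superior vertex is placed *exactly* at `length_total`;
- landmarks are made by exact vertex displacement: the three posterior
  support points (two condylar, one greater trochanter) end exactly
  coplanar at y = 0, the two distal condylar points exactly coplanar at
  z = 0 with midpoint x = 0, and a small anterior-medial epicondyle marker
  breaks mirror symmetry. The greater trochanter sits just below the neck
  so that the head sphere cannot become a posterior rolling contact. Ring
  vertices carry a fixed irrational phase offset so no hull facet is an
  accidental symmetric sliver. The generator verifies that the center of
  mass projects inside the posterior support triangle and errors
  otherwise;
- right femurs are exact mirror images (x -> -x with reversed winding) of
  the left construction.

`make_cohort_table()` simulates the statistics side: gender-stratified
demographics (male fraction 0.69; male/female heights 1.69/1.58 m, ages
64/70 y, weights 69/62 kg), femoral length linear in height (calibrated to
a height–length correlation of ~0.85), and RFC and banking from linear
models with Gaussian noise. The default RFC model is
`267.36 + 2.23*length - 2.88*banking + 57.49*laterality - 50.3*gender`
with residual SD 190 mm — the residual implied by a population SD of
211.68 mm and a model R^2 of 0.191. The banking model
(`59.69 + 5.7*gender + 0.236*age + 0.157*weight`, residual SD 11 deg)
folds a small RFC term into its intercept so that the simulation is
acyclic (banking is drawn first, then RFC given banking). Gender is coded
female = 1 / male = 0 and laterality left = 1 / right = 0; with this
coding the signs of the default coefficients are internally consistent
(males and left femurs have larger RFC). The coding is an inference — the
convention is rarely printed — and both it and the coefficients are
plainly overridable.

What the generator does **not** emulate: femoral neck anteversion, real
condylar geometry, the linea aspera, non-circular or multi-radius bows,
anterior-posterior cortical thickness asymmetry, segmentation noise, or CT
slice anisotropy. Passing tests therefore demonstrate that the *pipeline*
recovers the parameters of bones that satisfy the single-circle model
exactly; they do not certify accuracy on pathological or strongly
non-circular anatomies.

## Numerical choices

- **Circle fitting** uses the algebraic (Kasa) linearization only as an
  initializer and refines by geometric least squares (Gauss–Newton with
  Levenberg damping) to a relative tolerance of 1e-10, because algebraic
  fits are biased on short noisy arcs and mid-shaft canal arcs span only
  ~16–25 deg. Non-convergence after 200 iterations returns the algebraic
  fit with a warning. The fitted plane normal's sign is fixed (medial
  component >= 0, ties broken anterior then superior) so results are
  reproducible run to run.
- **Cross-sections** are computed once per mesh edge, so chained section
  loops are exact and slicing many stations reuses one edge table.
- **Inscribed circles** maximize distance-to-boundary over a refined grid
  rather than using the centroid-to-boundary distance, matching the
  "largest circle that fits" definition even for non-convex sections.
- **Centerline ordering** is proximal-to-distal. In the standardized frame
  the caller passes `orient = c(0, 0, 1)`; without a hint the wider canal
  end leads, a rotation-invariant rule that makes extraction equivariant
  under rigid motions of the input.
- **Isthmus ties** break toward the most proximal station.
- **Degenerate inputs** are flagged, not silently accepted: spheres settle
  with a `single_point_contact` flag, collinear point sets raise
  degeneracy errors, zero-variance samples yield degenerate test results
  (`p = 0` for the normality screen; an infinite-t flag for constant
  non-zero paired differences), and perfectly collinear predictors get
  infinite variance-inflation factors.
- **Lilliefors correction**: the naive asymptotic Kolmogorov–Smirnov
  p-value treats the normal parameters as known and is anti-conservative
  when they are estimated from the sample. The primary p-value is
  therefore Monte-Carlo, from a cached null table of the statistic under
  estimated parameters; the naive value is reported alongside for
  comparison with software that prints it.

## Statistical power of the cohort regression

The package's own calibration runs (see `scripts/acceptance.R`) show that
with cohorts simulated at the default noise level (R^2 ~= 0.19) and 426
femurs, stepwise selection at p-to-enter 0.05 retains the femoral-length
and banking terms almost always, but the weaker gender term (partial
t ~= 2.2 after adjusting for its correlation with length via height) in
only about half of replicates; all three jointly in roughly 0.4. This is a
property of the signal-to-noise ratio, not of the selection algorithm: on
strong-signal designs the same algorithm agrees with an exhaustive
best-subset oracle in > 95% of replicates, and its type-I behaviour
(admitting pure noise) is at the nominal 5%. Single-study regression
equations at this R^2 should be expected to change composition under
replication.

Two further statistical notes. First, the classic two-means sample-size
formula with alpha = 0.05, power = 0.80, SD 20 and difference 10 gives 63
per group by the normal approximation and 64 by the noncentral-t
refinement; published minima of ~85 per group for this design likely
include drop-out inflation or a different formula, and cannot be
reproduced from the stated inputs. Second, cohorts contain two femurs per
subject; the regression treats them as independent (as is conventional in
this literature), which understates standard errors slightly — a
mixed-effects treatment is out of scope and flagged as a limitation.

## Problem sizes used by the tests

The test-suite and acceptance runs use a 3 x 3 x 3 grid of synthetic
femurs (RFC 700/1000/1400 mm, banking 75/90/105 deg, isthmus 8/10/12 mm —
bracketing the observed anatomical ranges), 10 random rigid poses for
invariance, 20 noisy short arcs against a 100-start brute-force circle
minimizer, 2000 replicates for type-I calibration and power, and 100
simulated cohorts of 426 femurs for selection behaviour. Meshes default to
37 circumferential x 110 axial segments, at which the end-to-end recovery
errors are ~0.001% in RFC, < 0.001 deg in banking and < 0.05 mm in isthmus
diameter — comfortably inside the tolerances asserted by the tests (0.5%,
0.5 deg, 0.1 mm).

## Known limitations

- The single-circle model ignores proximal/distal variation of the bow;
  the three-section analysis exists precisely to expose it, but automatic
  anatomical landmarking of the section bounds (lesser trochanter,
  condylar flare) is not implemented — bounds are caller inputs.
- Femoral neck anteversion and all proximal-femur morphology beyond a
  schematic head are out of scope.
- The settling contract assumes a femur-like geometry: a posterior
  three-point support whose triangle contains the center-of-mass
  projection, and a head-heavy proximal end. Exotic shapes should use
  explicit `down` directions and inspect the returned transform.
- Clearance uses signed-distance sampling on a parametric torus; it
  reports a margin in mm but does not simulate nail insertion paths or
  elastic deformation.
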