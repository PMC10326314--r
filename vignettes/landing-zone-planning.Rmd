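---
title: "Landing-zone localization, sizing and C-arm angulation planning for LAA closure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landing-zone localization, sizing and C-arm angulation planning for LAA closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laaplan)
```

## The problem

Percutaneous left atrial appendage closure (LAAc) anchors an occluder device
at a *landing zone* — a cross-section of the appendage neck. Selecting the
device size requires the landing-zone diameters; guiding the implantation
requires a C-arm working projection in which that cross-section is seen
edge-on, so its maximal diameter projects without foreshortening.
Periprocedurally these quantities are measured on 2D fluoroscopy (XR) and
transesophageal echo (TEE); preprocedural 3D imaging can supply them in
advance if its measurements can be placed at the *same anatomical location*
as the intraprocedural ones and translated into the projective geometry of
the C-arm.

`laaplan` implements that translation as reusable, testable geometry:

1. **Localization** (`localizeLandingZone`): a landing-zone annotation made
   on an XR frame — two endpoints of a measured diameter, in detector
   coordinates — is back-projected into 3D. Each endpoint defines a
   projection line from the x-ray source; intersecting those lines with a
   registered 3D surface model of the appendage wall yields candidate wall
   points, and the chosen pair fixes the landing zone in 3D.
2. **Sizing** (`planeSection`, `sizingFromSection`): the cross-section plane
   through the localized diameter is intersected with the mesh and the
   resulting contour is measured: maximum diameter $d_{max}$, minimum
   diameter $d_{min}$, perimeter-derived diameter $d_{peri} = p/\pi$,
   area-derived diameter $d_{area} = 2\sqrt{a/\pi}$, and ovality
   $d_{max} - d_{min}$.
3. **Angulation prediction** (`optimalAngulation`): the beam direction
   $v = \pm\,\hat n \times \hat d_{max}$ lies in the section plane and is
   orthogonal to the maximal diameter — the unique (up to sign) projection
   that shows the landing zone edge-on with $d_{max}$ at true length.
4. **MPR** (`mprResample`): image volumes are reformatted on the landing
   plane by trilinear interpolation, reproducing the 2D view on which a
   reader would re-measure.
5. **Agreement statistics** (`blandAltman`, `pairedCompare`,
   `pearsonCorrelation`, `icc21`): the method-comparison toolkit used to
   assess such workflows — Bland-Altman bias and limits of agreement,
   Pearson correlation, paired-test selection driven by Shapiro-Wilk
   normality (paired *t* vs Wilcoxon signed-rank, Levene's statistic
   reported alongside), and ICC(2,1) with the F-based confidence interval of
   the single-rating absolute-agreement two-way random-effects model.

Because clinical image data of this kind are access-restricted, the package
validates itself on **synthetic phantoms with analytic ground truth**
(`generatePhantom`): every measured quantity has a closed-form or quadrature
value to recover.

## Projection model

The patient frame is DICOM LPS (+x left, +y posterior, +z superior). A
C-arm pose carries the primary angle $\alpha$ (positive LAO, negative RAO),
the secondary angle $\beta$ (positive CRAN, negative CAUD), the
source-to-isocenter distance (SOD, default 765 mm) and source-to-detector
distance (SID, default 1100 mm) of a typical interventional system. The
central beam direction is

$$ v(\alpha, \beta) = (\sin\alpha \cos\beta,\; -\cos\alpha \cos\beta,\; \sin\beta), $$

so AP is $(0,-1,0)$ and the clinically recommended working range
RAO20-30/CAUD20-30 maps to $\alpha, \beta \in [-30°, -20°]$. Projection is
cone-beam: a point at depth $z$ from the source maps to the detector with
magnification SID$/z$. Setting SID $= \infty$ gives a parallel-projection
mode with closed-form behavior, used in analytic tests. The detector frame
is fixed by the convention that the row axis is the horizontal patient axis
rotated by $\alpha$; detector rotation about the beam axis is out of scope,
which costs nothing here because all derived quantities (distances along
the annotated segment, back-projected lines) are invariant to it.

Angle separation between two poses is always computed as the 3D angle
between beam directions (`angularDifference`), not as a Euclidean distance
in $(\alpha, \beta)$, which overstates separation away from the equator.
The atan2 form is used instead of `acos` for full precision near 0° and
180°.

## Localization rules the data do not dictate

Two steps of the localization are genuinely underdetermined by the
workflow's description, and are therefore isolated behind small functions
with documented conventions:

* **Hit-pair selection.** A projection line through a tubular anatomy can
  cross the wall 2 or 4 times. Among all pairs (one hit per annotation
  ray), the pair minimizing the absolute depth difference along the beam is
  selected: the endpoints of a measured diameter lie on opposite walls at
  the same depth. An alternative (nearest to a prior landing-zone estimate)
  could be slotted in at `localizeLandingZone`.
* **Plane construction** (`landingPlane`). The cross-section plane is taken
  to contain the localized segment and the beam:
  $\hat n = \widehat{(b - a) \times v}$. Under the ideal tangential view
  both the measured diameter and the beam lie in the anatomical
  cross-section plane, so this reconstructs it exactly; away from the ideal
  view it degrades gracefully (the plane tilts with the view). A
  centerline-orthogonal construction would be a drop-in alternative but
  requires a centerline, which is deliberately out of scope.

## Sizing definitions

Perimeter and area are measured on the raw section contour; $d_{max}$ and
$d_{min}$ are computed on its convex hull (the maximal chord of a closed
region equals that of its hull, and hull calipers match clinical caliper
practice; `polygonMinWidth` is the rotating-calipers support width). The
derived diameters are the diameters of the circles with the contour's
perimeter and area:

$$ d_{peri} = p / \pi, \qquad d_{area} = 2\sqrt{a/\pi}. $$

On a circle all four coincide — the anchor identity the test suite checks
to 0.1% at 512-segment resolution.

For convex sections the provable ordering is
$d_{area} \le d_{peri} \le d_{max}$ (isoperimetric inequality; Cauchy's
formula $p = \pi \times$ mean width, and mean width $\le$ diameter)
together with $d_{min} \le d_{peri}$ (min width $\le$ mean width). The
tempting full chain $d_{min} \le d_{area}$ is **not** a theorem: an
equilateral triangle of side $s$ has support width $0.866\,s$ but
$d_{area} = 0.742\,s$, and near-constant-width sections behave the same
way. It does hold for ellipses ($d_{area} = 2\sqrt{ab} \ge 2b$), hence for
every phantom section; the suite asserts exactly that split and keeps the
triangle counterexample as a regression test.

## The phantom generator

`PhantomSpec` describes a tube: a straight or circular-arc centerline of
length $L$ (default 60 mm), elliptical cross-sections with semi-axes
$a(s), b(s)$ tapering linearly in normalized arc length, an optional linear
twist of the section orientation, and a designated landing position
$s^\ast \in (0,1)$. Ends are capped, so meshes are watertight. Ground truth
at $s^\ast$ — plane, $d_{max} = 2a$, $d_{min} = 2b$, area $\pi a b$,
perimeter by quadrature, the max-diameter direction and the ideal
tangential pose — comes from the parametric definition, never from the
mesh.

Default conditions mirror the emulated clinical setting: landing-zone
diameters 16-30 mm (major semi-axis 8-15 mm, axis ratio 0.6-1, i.e.
ovality 0 to ~12 mm), voxel size 1.3 mm isotropic for voxelized volumes,
SOD/SID 765/1100 mm, and working projections sampled within
RAO20-30/CAUD20-30. The study cohort size is 13 cases. Mesh resolution
128 x 64 gives sub-0.1% section metrics (the suite verifies 1% at 128 and
0.1% at 512 circumferential segments, matching the $O(h^2)$ chordal error).

What the phantoms deliberately do **not** model: real LAA morphology
classes (chicken-wing, cauliflower, ...), lobes, wall thickness, imaging
noise or motion, segmentation error, and registration error between mesh
and XR frame (the mesh is taken as already registered; `registerPoints`
provides the rigid alignment primitive and is tested separately). Passing
phantom tests therefore demonstrates the *geometric* correctness of the
pipeline, not robustness to segmentation or registration failure.

### Annotation simulation and the silhouette inset

`simulateAnnotation` projects the true maximal-diameter wall endpoints and
pulls each endpoint slightly inward along the annotated segment
(`inset_mm`, default 0.05 mm in detector units). The inset exists because
the faceted mesh is inscribed in the analytic surface: a ray through the
exact analytic silhouette point can pass outside every facet (facet sag is
~5 µm at 128 segments), whereas a reader annotates the silhouette edge
actually visible in the image. The geometry sets the scale of the induced
error: a grazing ray displaced inward by $\delta$ meets the wall a lateral
distance $\approx \sqrt{2\delta/\kappa}$ from the true apex, with apex
curvature $\kappa = a/b^2$. At $\delta = 0.05$ mm detector
($\approx 0.035$ mm at isocenter) the worst case over the phantom family
(large, near-circular sections, $\kappa \approx 0.067$/mm) is ~1.0 mm —
inside the one-voxel (1.3 mm) acceptance band, and two orders above the
facet sag the inset must clear. The same square-root law means *noisy*
annotations are localized with errors dominated by
$\sqrt{2\,\sigma_{\mathrm{eff}}/\kappa}$, i.e. flat-apex (circular)
sections localize worse than sharply oval ones; with noise the simulated
reader marks the inner lumen edge conservatively (inset grows as
$0.05 + 2\sigma$) so the grazing rays stay on the silhouette, and the few
annotations that still miss are excluded per case — as unusable XR would
be clinically.

Straight centerlines (with taper, twist and ovality variation) are used
for the localization round-trip studies; arc centerlines are supported and
tested for generation and sectioning, but a strongly curved tube can put
additional wall crossings on a grazing ray, where the depth-disparity
selection rule alone is not a complete disambiguation.

## Numerical choices

* Ray-triangle intersection is the vectorized Möller-Trumbore test with
  inclusive barycentric bounds; hits within $10^{-6}$ mm are merged, so
  rays through shared edges or vertices count once. Exterior rays through
  watertight meshes then report even hit counts, which voxelization
  (`voxelize`) exploits via axis-parallel parity casting.
* Plane sectioning nudges vertices lying exactly on the plane by a relative
  $10^{-12}$ so every crossing is transversal; segments are chained into
  loops on a $10^{-9}$-relative snapping grid, and open chains (possible
  only on non-watertight input, which is warned about) are dropped.
* `registerPoints` is the SVD (Kabsch) solution with reflection correction;
  a mirrored target is answered with the best proper rotation, never a
  reflection.
* MPR interpolation is trilinear with fill 0 — exact for affine intensity
  fields, which the tests exploit; coordinates use the center-of-voxel
  convention throughout, matching NIfTI. Volumes are kept in LPS
  internally; NIfTI xforms are RAS, so the first two axes are negated on
  I/O.
* The Wilcoxon branch drops zero differences and uses the exact null for
  $n \le 25$ (no ties), the normal approximation with continuity correction
  otherwise — at the $n = 11\text{-}13$ scale of such studies the exact
  distribution matters. Identical series return $p = 1$ on the *t*-branch
  by convention and are flagged degenerate.
* ICC(2,1) is computed from the two-way ANOVA mean squares
  $(MSR - MSE) / (MSR + (k-1)MSE + \tfrac{k}{n}(MSC - MSE))$ with the
  McGraw-Wong F-based confidence interval; the suite checks it against a
  brute-force double-loop ANOVA to $10^{-10}$ and against simulated
  variance components ($\sigma^2_s = 9, \sigma^2_r = 0.25,
  \sigma^2_e = 1 \Rightarrow 0.878$).
* The two antiparallel solutions of the angulation prediction are
  disambiguated toward RAO25/CAUD25, the center of the recommended working
  range — clinical access favors that quadrant. The >10° agreement
  threshold (strict, with $10^{-9}$ float slack) is configurable; its
  default reflects reported inter-reader variability of such predictions
  (mean 7.6° ± 4.2°, CI up to 9.9°).

## Worked example

```{r example}
spec <- PhantomSpec(semi_a_mm = 15, semi_b_mm = 10, twist_deg = c(0, 15))
ph <- placePhantom(generatePhantom(spec), CArmPose(-25, -25))
pose <- ph$truth$tangential_pose
ann <- simulateAnnotation(ph, pose)
zone <- localizeLandingZone(ph$mesh, pose, ann$q_a, ann$q_b)
sec <- measureCrossSection(ph$mesh, zone)
sizingFromSection(sec, source = "XR-located")
optimalAngulation(sec@plane_normal,
                  ph$truth$dmax_direction, reference = pose)
```

```{r study}
st <- runPhantomStudy(n_cases = 13, seed = 7)
st$accuracy$agreement[, c("comparison", "deviation", "correlation")]
print(st$planning$confusion)
```

## Problem sizes

The shipped validation uses 13-case studies, 25-phantom localization
sweeps, 128 x 64 meshes (512 circumferential segments for the circle
identity), 200 random convex sections, 1000 projection round trips, and
simulated panels of 2000-5000 subjects for the statistics — sizes at which
every oracle is sharp while a full run stays comfortably interactive on a
single core.

## Known limitations

* Registration is assumed done; errors in it propagate directly into
  localization and are not modeled.
* Detector rotation about the beam axis, table offsets and distortion are
  not modeled (invariant or out of scope, see above).
* `measureCrossSection` picks the loop nearest the landing-zone midpoint;
  pathological lobed sections where the anatomical loop is farther than a
  neighboring lobe would need the centerline context the package avoids.
* The sizing-chart lookup ships no vendor chart: published charts are
  calibrated for TEE-based measurements, and applying them to 3D-derived
  diameters is a clinical decision, not a computation.
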