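---
title: "Measuring head-taper slip with radiostereometry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring head-taper slip with radiostereometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsataper)
```

## The measurement problem

Roentgen stereophotogrammetric analysis (RSA) measures implant motion
relative to bone at sub-millimetre accuracy from simultaneous paired
X-rays taken over a calibration box. In total hip arthroplasty the modular
femoral ball head sits on a conical stem trunnion ("taper"); wear and
corrosion at this junction (trunnionosis) let the head creep onto and
around the taper by tenths of a millimetre over years. `rsataper`
implements the complete measurement chain needed to quantify that slip:

1. **Stereo calibration and reconstruction** — recover each X-ray focus
   from calibration-box observations, then triangulate digitized 2D marker
   images into 3D positions.
2. **Rigid-body kinematics** — SVD point registration between a reference
   and a follow-up exam, the RSA quality numbers (condition number,
   rigid-body error), Euler angles and reference-point handling.
3. **EGS pose fitting** — the ball head as a sphere of known radius fitted
   to silhouette contours; the taper and stem body as cones fitted to
   silhouette lines.
4. **Head-taper migration** — the head centre's motion relative to the
   stem body, expressed in a taper-aligned coordinate frame.
5. **Method-comparison statistics** — Bland-Altman limits of agreement
   against RSA accuracy thresholds, one-sample t-tests, Pearson
   correlation with Fisher-Z inference.
6. **A synthetic phantom generator** that emulates a long-term clinical
   follow-up cohort with known ground truth.

Because no patient radiographs are publicly available for this kind of
study, the phantom is a first-class module: every quantitative claim the
test suite makes is a recovery of a *known* programmed truth, not a
reproduction of clinical values.

## Imaging model

The global frame is the calibration-box frame: the film plane is `z = 0`,
+x medial, +y cranial, +z anterior for a right hip (left hips are mirrored
in x at ingest). Two foci sit at `z = 1400` mm (the 140 cm film-focus
distance), placed symmetrically at `x = ±1400·tan(20°)` so the central
rays intersect at 40° — the uniplanar two-exposure setup. Projection is a
central projection onto `z = 0`.

**Calibration.** The synthetic box carries 3×3 fiducial beads in the film
plane (60 mm pitch) and 3×3 control beads in an elevated plane (55 mm
pitch). Commercial box layouts are proprietary; any non-degenerate
two-plane layout satisfies the mathematics. The film mapping from
digitized to film-mm coordinates is a least-squares 2D affinity (the film
lies in the fiducial plane, so 6 dof suffice; an 8-dof homography is
available via `model = "projective"`). The focus is the least-squares
intersection of the control rays. Two declared error metrics gate the
exam: `calibration_error`, the RMS fiducial residual after the mapping,
and `focus_error`, the RMS perpendicular distance from the fitted focus to
the control rays. The commercial software's exact formulas are
unpublished; these definitions are ours and are what the 0.05 mm / 0.5 mm
gates apply to.

**Control-plane height.** The focus-error metric amplifies film-plane
noise by roughly `(h_focus − h_control)/h_control`. At a control height of
80 mm that factor is ≈ 17, and the 0.5 mm focus gate would be unpassable
at a realistic 0.05 mm contour digitization noise; at the default 200 mm
the factor is ≈ 6 and the standard gates behave as intended. This is a
deliberate design choice of the synthetic world.

**Noise model.** i.i.d. isotropic Gaussian noise on every digitized 2D
coordinate, with two scales: `noise_sigma_2d` (default 0.05 mm) for
markers, landmarks and silhouettes, and `noise_sigma_box` (default
`min(0.01, noise_sigma_2d)`) for the calibration-box beads, which are
high-contrast spheres and digitize better than implant contours in
practice. No detection bias, no occlusion, no film distortion — all
declared simplifications.

## Rigid-body kinematics

`fit_rigid_body()` is the standard SVD (Kabsch/Arun) least-squares
registration with reflection correction (the sign of the last singular
vector is flipped when `det < 0`). Conventions, all switchable but fixed
for the tests:

* **Rigid-body error** = RMS residual after the fitted transform (not
  mean absolute, and a fit residual rather than a marker-distance change —
  the alternative reading of the published threshold). The 0.35 mm gate
  applies to the maximum of the bone-fit and implant-fit residuals of an
  exam pair.
* **Condition number** = `100 / σ₂` with `σ₂` the middle singular value
  (in mm) of the centred marker configuration. Planar 3-marker bodies are
  admissible; collinear sets give `Inf` and fail the ≤ 100 gate, which is
  the gate's intent. The exact commercial definition is unpublished.
* **Euler order** `R = Rz·Ry·Rx` (x applied first), reported in degrees
  about the medial-lateral, cranial-caudal and anterior-posterior axes.
  Near-gimbal configurations (`|Ry| → 90°`) are flagged, not errored.
* **Reference points**: translations are the displacement of a declared
  reference point. The marker pipeline uses the tantalum-marker centroid;
  the EGS pipeline uses the virtual-marker centroid, and
  `correct_reference_point()` (the Hurschler correction,
  `d(new) = d(old) + (R − I)(new − old)`) re-expresses EGS translations at
  the marker centroid so the two pipelines are comparable.

## EGS fitting

**Sphere.** Each silhouette contour point back-projects to a ray tangent
to the head sphere, so the centre is found by least squares on tangency
residuals — distance from centre to ray minus the known 14 mm radius —
summed over one or two views. This is an equivalent reformulation of
"distance between the observed contour and the projected silhouette
ellipse": both vanish at the true centre, and at small noise they differ
by a smooth local scale factor only. Initialization is closed-form from
the viewing cone of the contour rays (centre at `radius/sin(half-aperture)`
along the mean ray). A single view suffices because the known radius fixes
depth; two views are the default. Contours with fewer than 8 points are
rejected.

**Cone.** Every tangent plane of a cone passes through its apex. Each
observed silhouette line spans, with its view's focus, such a tangent
plane; with two views there are up to four planes. The apex is the
least-squares intersection of the planes, and the axis direction `a` and
half-angle `θ` minimize the squared angular residuals
`asin(|nᵢ·a|) − θ`. The initial axis is exact at zero noise: with
consistently oriented (outward) normals, `a` is orthogonal to the
difference of each view's two normals. The stem body is handled by the
same fitter — its silhouette is a cone of small half-angle (2° in the
phantom), and only its axis line is consumed downstream.

**Virtual markers** (the EGS stand-in for physical implant markers):
`P1` = head centre, `P2` = lowest point of the stem tip (a digitized
landmark reconstructed by stereo), `P3` = orthogonal projection of `P1`
onto the stem-body axis line. Their centroid is the EGS reference point.
A stable head-taper junction makes this triple a rigid body; head-taper
slip moves `P1` and `P3` relative to `P2`, deforming it — which is exactly
the mechanism by which slip biases EGS migration results, and what the
interchangeability analysis detects.

**Taper frame.** `Y` along the fitted cone axis, signed cranially; `X`
orthogonal to `Y`, parallel to the implant-marker plane, signed medially
(via the `side` flag — the published convention fixes "medial" verbally
but not left/right); `Z = X × Y`. Head-taper migration is the slip vector
`T⁻¹(h_fu) − h_ref` (with `T` the stem-marker transform), expressed in the
*reference* exam's taper frame — this removes all stem motion from the
slip and makes visit 0 exactly zero. The follow-up frame would differ by
the stem rotation; the choice is declared and deliberate.

## The synthetic phantom

The generator states a world once and the tests measure how well the
pipeline recovers it:

* **Anatomy**: a cemented stem with shaft along y, a neck/taper axis
  inclined 54° from the proximal shaft (CCD angle 126°), taper half-angle
  `5.611/2°`, a 28 mm ceramic head whose centre rides on the taper axis
  (head-neck lengths S/M/L shift it by 2/4/6 mm), three tantalum implant
  markers on the stem body, six bone markers, and a stem tip landmark.
* **Schedule**: reference plus follow-ups at 1.5, 3, 6, 12, 24, 60 and
  120 months.
* **Trajectories**: a declared three-phase fraction table
  `{0, .05, .10, .20, .60, .90, .97, 1}` over the default schedule — slow
  embedding to 6 months, the majority of motion between 6 and 24 months,
  then a plateau. The published follow-up curves cannot be digitized from
  a figure; the fraction table reproduces the qualitative pattern, with
  amplitudes anchored to printed text values only. The default total slip
  `(0.10, −0.12, −0.21)` mm has 3D magnitude ≈ 0.26 mm at 10 years,
  i.e. ≈ 0.026 mm/year — the clinically reported order of magnitude.
  Implant-to-bone totals are `(0.05, −0.15, 0.05)` mm and
  `(0.1, 0.2, −0.1)°`, a stable cemented stem.
* **Per-patient variation**: lognormal amplitude multipliers
  (`sdlog = 0.3`, mean 1), 1 mm marker-placement jitter, random S/M/L
  assignment.
* **Repositioning**: the reference exam defines the global frame; each
  follow-up gets a random patient pose (±10 mm, ±1.5°). Applying a pose to
  the reference too would merely conjugate every recovered transform by
  it, making ground-truth parameters frame-dependent without exercising
  anything new.
* **Slip injection**: the head is displaced by the slip vector expressed
  in the reference taper frame and carried along by the stem rotation, so
  the pipeline's reference-frame slip estimate targets the programmed
  numbers exactly.
* **Determinism**: one seed in the config; per-patient seeds are drawn
  from it, so studies are reproducible patient-by-patient.

What a green test establishes: that the algorithms recover a known truth
through the full projective chain at realistic noise. What it does not
establish: anything about detector physics, contour-extraction bias,
marker occlusion, or the clinical distribution of slip — the phantom's
noise is idealized and its trajectory shapes are declared, not estimated.

## Statistics

Bland-Altman limits of agreement use `mean ± 1.96·sd` with the sample SD
(divisor n−1); the two RSA methods are "interchangeable" on an axis when
both limits lie within the upper limit of RSA accuracy — 0.5 mm for
translations, 1.15° for rotations. The in-vitro impaction table is
reproduced with the *population* SD rounded to integer micrometres (the
sample SD does not reproduce the printed values — both conventions are
returned by `descriptive_stats()`). The one-sample t-test and the
Pearson/Fisher-Z correlation (`z = atanh(r)·√(n−3)`) are computed from
their closed formulas and unit-tested against `stats::t.test()` /
`stats::cor.test()` as independent oracles. The method comparison is run
on the *reference-point-corrected* EGS results, matching the published
protocol; per-visit pooling uses the early (3-6 months) and late
(12-120 months) groups. Replicate readings of the same radiograph, where
present, would be averaged before analysis (no repeated-measures
correction; declared limitation). The cohort migration rate is defined as
the 3D magnitude of the mean slip vector at the final visit divided by
follow-up years — the published per-year figure does not define its norm,
so ours is declared and per-axis rates are emitted alongside.

## Numerical choices and degenerate inputs

* Gate boundaries are inclusive (`≤`), matching the published notation.
* Collinear marker sets: registration errors out; `condition_number()`
  returns `Inf` (the gate handles it).
* Sphere fit: BFGS on 3 parameters; a restart is accepted when the
  objective is at numerical zero or no longer improves (BFGS can exhaust
  iterations dithering at machine precision). Non-convergence is an error
  with diagnostics, and such exams are flagged out of summaries.
* Cone fit: near-parallel tangent planes (taper seen end-on) and
  unresolvable axis directions are errors, as is a non-positive fitted
  half-angle.
* Triangulation: near-parallel rays error; the crossing distance of every
  reconstructed point is reported as a per-point quality metric.
* Missing visits are allowed; summaries use available-case analysis.

## Worked example

```{r example, eval = FALSE}
cfg <- phantom_config(n_patients = 4, seed = 42)
study <- generate_study(cfg)

ht <- headtaper_table(study)
cohort_summary(ht)$rate_mm_per_year      # ~0.026 mm/year by construction

mig <- migration_table(study, methods = c("marker", "egs_corrected"))
interchangeability_analysis(mig, ht, egs_method = "egs_corrected")
```

The README shows the same pipeline with the numbers it actually prints.

## Known limitations

* No pixel-level image processing: inputs are digitized coordinates.
* No CAD/RE surface-model matching — elementary geometrical shapes only.
* No occlusion or visibility model for contours (hard-soft bearings are
  assumed to show the full head outline).
* The phantom's slip distribution is an order-of-magnitude choice anchored
  to printed summary values, not a fitted patient population.
* No survival modelling, clinical decision rules, or DICOM ingestion.
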