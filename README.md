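# rsataper

Radiostereometric analysis (RSA) of implant migration in total hip
arthroplasty, with a focus on measuring **head–taper slip**: the creeping
motion of the modular femoral ball head on the stem's conical trunnion
("trunnionosis"). The package implements the full measurement chain —
stereo X-ray calibration and triangulation, rigid-body migration
kinematics, elementary-geometrical-shape (EGS) pose fitting of the sphere
head and cone taper, the taper-axis slip measurement, Hurschler
reference-point correction, and the marker-based vs model-based
interchangeability statistics — together with a ground-truth-paired
synthetic phantom generator, because clinical RSA radiographs of this kind
are not publicly deposited.

## Who this is for

Biomechanics and orthopaedic-imaging researchers who want a tested,
scriptable RSA computation core: to prototype study designs, to validate
analysis choices against a phantom with known truth, or to process
digitized exam data in the package's JSON dialect.

## The core computations

* **Calibration** (`calibrate_view`): a least-squares planar mapping from
  digitized to film coordinates fitted on fiducial beads, and the focus
  position as the least-squares intersection of control-bead rays.
  Quality: RMS fiducial residual ≤ 0.05 mm, RMS focus-to-ray distance
  ≤ 0.5 mm.
* **Reconstruction** (`reconstruct_point`): midpoint of the common
  perpendicular of the two back-projected rays; the crossing distance is a
  per-point quality metric.
* **Migration** (`fit_rigid_body`, `euler_angles`,
  `migration_of_point`): SVD point registration `fu ≈ R·ref + t`
  (reflection-corrected), Euler decomposition `R = Rz·Ry·Rx` in degrees,
  translations as the displacement of a declared reference point.
  Quality: condition number `CN = 100/σ₂` ≤ 100 and rigid-body error
  (RMS fit residual) ≤ 0.35 mm.
* **EGS fits** (`fit_sphere_center`, `fit_cone_axis`): the head centre
  from silhouette-ray tangency to a sphere of known radius (14 mm for a
  28 mm head); the taper axis and half-angle (5.611°/2) from the tangent
  planes spanned by silhouette lines, the apex being common to all
  tangent planes.
* **Head–taper slip** (`head_taper_migration`): with `T` the stem-marker
  transform from reference to follow-up and `h` the fitted head centre,
  the slip is `T⁻¹(h_fu) − h_ref`, reported in the reference taper frame
  (Y along the taper axis, X medial in the implant-marker plane,
  Z = X × Y).
* **Method agreement** (`bland_altman`, `one_sample_t`,
  `correlate_diff_vs_slip`): limits of agreement `mean ± 1.96·sd` judged
  against the RSA accuracy thresholds (0.5 mm / 1.15°), one-sample t on
  intermethod differences, Pearson r with Fisher-Z inference
  (`z = atanh(r)·√(n−3)`).

## Worked example

Generate a small synthetic cohort (4 patients, default world: ~0.26 mm
total slip by 10 years, 0.05 mm contour noise), measure slip, and run the
interchangeability analysis:

```r
library(rsataper)

cfg   <- phantom_config(n_patients = 4, seed = 42)
study <- generate_study(cfg)

ht <- headtaper_table(study)
cs <- cohort_summary(ht)
round(cs$rate_mm_per_year, 4)
#> [1] 0.0286
cs$summary[cs$summary$visit_months %in% c(6, 24, 120),
           c("visit_months", "n", "dx_mean", "dy_mean", "dz_mean")]
#>   visit_months n dx_mean dy_mean dz_mean
#> 4            6 4   0.064  -0.001  -0.066
#> 6           24 4   0.154  -0.086  -0.093
#> 8          120 4   0.151  -0.111  -0.216
```

The cohort slips ≈ 0.029 mm/year (3D magnitude of the mean 10-year slip
vector / 10), mostly between 6 and 24 months — the programmed three-phase
pattern, recovered through the full projective chain at 0.05 mm noise.
Comparing marker-based migration against the reference-point-corrected
EGS result shows the slip leaking into the model-based method
(cranial-caudal axis shown; `mean_diff` in mm, `r` against measured
slip):

```r
mig <- migration_table(study, methods = c("marker", "egs_corrected"))
cmp <- interchangeability_analysis(mig, ht, egs_method = "egs_corrected")
cmp[cmp$axis == "Ty", c("n", "mean_diff", "loa_lower", "loa_upper", "t", "p_t", "r")]
#>    n mean_diff loa_lower loa_upper       t    p_t      r
#> 2  8   -0.0378   -0.0907    0.0150 -3.9694 0.0054 0.3745   # 3-6 months
#> 8 16   -0.1220   -0.2357   -0.0084 -8.4210 0.0000 0.8559   # 12-120 months
```

The late-group bias is significant and strongly correlated with the
head-taper migration, while both groups stay within the 0.5 mm agreement
threshold — the mechanism by which slip can masquerade as stem
instability in model-based RSA.

## Command line

```sh
exec/rsataper simulate --seed 5 --out run1          # write a study (JSON exams + ground truth)
exec/rsataper headtaper --run run1 --out results    # slip CSV
exec/rsataper migrate   --run run1 --out results    # 6-DoF migration CSV (3 methods)
exec/rsataper compare   --run run1 --out results    # interchangeability CSV
exec/rsataper report    --run run1 --out results    # cohort summary + rate
```

A YAML config (`--config`) can override any phantom default. See
`vignettes/rsataper-methods.Rmd` for the model, its assumptions, the
declared conventions (error metrics, Euler order, SD conventions,
reference frames) and the known limitations.
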