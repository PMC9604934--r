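# glenax

Glenoid inclination from 3D scapular models, and how much the choice of the
scapular **transverse axis** changes it.

Glenoid inclination — the signed angle, in the scapular frontal plane,
between the transverse axis and the glenoid mediolateral axis (positive =
superiorly tilted glenoid) — drives implant-positioning decisions in
shoulder arthroplasty, yet planning systems construct the transverse axis in
different ways.  `glenax` is for musculoskeletal-imaging researchers and
planning-software developers who want to measure the angle on segmented
scapulae and quantify how the axis definition, and inter-rater landmark
variability, propagate into it.

The package implements, on a region-labeled triangle mesh of the scapula:

* the three transverse-axis constructions in common use:
  * **Y-axis** — best-fit line to all points at the intersection of the
    scapular spine and body, translated to the glenoid center (fully
    automated);
  * **GT line** — line from the picked trigonum to the glenoid center;
  * **BFLF** — best-fit line to five picks along the bottom of the
    supraspinatus fossa;
* the shared ingredients: total-least-squares frontal plane (all vertices
  except glenoid, acromion, coracoid), apex-midpoint glenoid center, and the
  glenoid mediolateral axis from a geometric least-squares sphere fit to the
  glenoid surface, with the inclination

  `inclination = signed angle( proj_F(transverse), proj_F(glenoid axis) )`

  measured in the frontal plane `F` with an explicit, laterality-invariant
  sign convention;
* a parametric **synthetic scapula** with closed-form ground truth and a
  four-rater Gaussian landmark-noise simulator (anisotropic trigonum noise,
  5 mm superoinferior / 2 mm otherwise);
* the **agreement statistics** used to compare methods: ICC(2,1) with
  F-based confidence intervals, Bland–Altman limits of agreement, Lin's
  concordance coefficient with its lack-of-precision / lack-of-accuracy
  split (LoP + LoA = 100%), a staged concordance workflow (r > 0.7 gate,
  3° bias / 5° limit thresholds), power-based minimum sample size, and
  lone-outlier discrepancy counts.

## Worked example

```r
library(glenax)

# a synthetic scapula with true inclination 10 deg and a 10 mm superior
# displacement of the trigonum (a "worst-case" medial border)
cs  <- generateScapula(scapulaParams(trueInclinationDeg = 10, trigonumOffsetSi = 10))
res <- measureInclination(cs@mesh, cs@trueLandmarks)
round(vapply(res, inclinationDeg, numeric(1)), 2)
#>  y_axis gt_line    bflf
#>   10.00   15.71   10.00

minSampleSize(delta = 5, sd = 10)   # design power analysis
#> [1] 63
```

The automated Y-axis and the five-point BFLF recover the true 10°; the
two-point GT line, which runs through the displaced trigonum, overestimates
by `atan(10/100) = 5.71°` — the mechanism behind the large between-method
discrepancies seen on scapulae with variable medial-border anatomy.

A full simulated four-rater study (82 cases, default noise) and its report:

```r
res <- runStudy(studyConfig(nCases = 82, seed = 7))
summarizeStudy(res)
#> Inclination by transverse-axis method (rater-averaged):
#>      statistic y_axis gt_line  bflf
#>     Mean (deg)    4.0     3.9   3.9
#>  Minimum (deg)  -14.7   -15.9 -14.1
#>  Maximum (deg)   20.9    21.9  23.0
#>       SD (deg)   10.2    10.6  10.4
#>
#> Interobserver ICC (per-rater values):
#>                 method  icc ci_low ci_high
#>                 Y-axis 1.00   1.00    1.00
#>  Glenoid-Trigonum line 0.93   0.90    0.95
#>    Best-fit line fossa 0.94   0.91    0.95
#>
#> Between-method concordance (rater-averaged values):
#>               pair    r bias_deg loa_low loa_high ccc lop_pct loa_pct    verdict
#>  y_axis_vs_gt_line 0.98      0.1    -3.6      3.7  NA      NA      NA concordant
#>    bflf_vs_gt_line 0.98      0.0    -4.1      4.0  NA      NA      NA concordant
#>     y_axis_vs_bflf 0.99      0.1    -2.5      2.7  NA      NA      NA concordant
#>
#> Lone-outlier cases (>= 5 deg from both other methods): Y-axis 0, GT-line 1, BFLF 0
#> Pairwise discrepancy rates >= 5 deg: Y vs GT 1%, Y vs BFLF 0%, GT vs BFLF 2%
```

The automated method's ICC is exactly 1.00 (it ignores rater landmarks);
the manual methods sit below it, with the two-point GT line lowest.  Lin's
fields are `NA` here because all three pairs pass the Bland–Altman
thresholds, in which case the staged workflow deliberately skips the Lin
stage.

Meshes travel as ASCII PLY (region labels embedded), STL or OBJ with a label
sidecar CSV; landmarks as JSON or CSV (`readScapulaMesh()`,
`readLandmarks()`, and the matching writers).

See `vignette("glenoid-inclination")` for the model, conventions, noise
calibration and known limitations of the flat-blade simulation.

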