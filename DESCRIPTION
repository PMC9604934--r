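Package: glenax
Title: Glenoid Inclination from 3D Scapular Models and Transverse-Axis
    Method Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures the signed glenoid inclination angle on labeled
    triangle meshes of the scapula by constructing the scapular frontal
    plane, the glenoid mediolateral axis (best-fit sphere to the glenoid
    surface) and three competing scapular transverse axes: the fully
    automated Y-axis (best-fit line to the spine/body intersection), the
    glenoid-trigonum line, and the best-fit line to five supraspinatus
    fossa landmarks.  Includes total-least-squares plane, line and sphere
    fitting, a parametric synthetic-scapula generator with closed-form
    ground truth and a multi-rater landmark-noise simulator, and the
    method-agreement statistics used to compare the axes: two-way
    random-effects ICC with F-based confidence intervals, Bland-Altman
    limits of agreement, Lin's concordance correlation coefficient with
    its precision/accuracy decomposition, a staged concordance workflow,
    power-based minimum sample size, and lone-outlier discrepancy counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils-internal.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'io.R'
    'axes.R'
    'synthetic.R'
    'agreement.R'
    'study.R'
    'glenax-package.R'
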