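Package: rvkin
Title: Right Ventricular Kinematics from Sonomicrometry Crystal Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of right-ventricular (RV) geometry and epicardial
    deformation from implanted sonomicrometry crystals recorded together
    with ventricular pressures and ECG. Detects cardiac-cycle landmarks
    (end-diastole at the R-wave peak, end-systole at maximum negative LV
    dP/dt), averages consecutive beats on a normalized time grid, and
    computes tricuspid annular area, convex-hull RV volume, regional
    cross-sectional area and radius of curvature, and regional
    circumferential, longitudinal and areal Green-Lagrange strains on a
    Loop-subdivided triangulated crystal mesh. Includes a deforming
    half-ellipsoid phantom generator with closed-form ground truth for
    validation, and paired Baseline-versus-annuloplasty cohort statistics
    (paired t, Shapiro-Wilk, exact Wilcoxon signed-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
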