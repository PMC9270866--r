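# rvkin — right-ventricular kinematics from sonomicrometry crystal arrays

`rvkin` analyses multichannel sonomicrometry recordings of the beating
right ventricle (RV): the 3D trajectories of 20 implanted crystals
(6 around the tricuspid annulus, 13 on the free wall along basal/mid/
lower parallels, 1 at the apex) sampled at 128 Hz together with LV,
RV and central venous pressures and ECG. It is written for
cardiovascular biomechanics groups comparing a Baseline state against
tricuspid ring annuloplasty (TRA) — or any other paired intervention
recorded with matched crystals.

The pipeline:

* **Cycle landmarks** — end-diastole (ED) at the R-wave peak,
  end-systole (ES) at maximum negative LV dP/dt; beats segmented per
  RR interval and 4 consecutive sinus beats averaged on a normalized
  0–100 % cycle grid.
* **Geometry** — tricuspid annular area (projected 6-point polygon),
  percent annular reduction `100·(1 − A_TRA/A_Baseline)`, convex-hull
  RV volume of all 20 crystals (ml), and per-parallel cross-sectional
  area and radius of curvature (least-squares circle fit).
* **Strain** — per-face Green–Lagrange strain `E = ½(FᵀF − I)` on a
  triangulated free-wall mesh refined by Loop subdivision (shared,
  linear operator for reference and deformed frames), resolved into
  circumferential and longitudinal components along the
  annular-centroid→apex axis, plus areal strain `det F − 1`.
  *Cardiac* strain references each state to its own ED across the
  cycle; *interventional* strain references TRA to Baseline at a
  matched time point.
* **Statistics** — paired t-test, exact Wilcoxon signed-rank
  (mid-ranks, zeros dropped, exact null distribution up to n = 25)
  and Shapiro–Wilk normality flags in a two-state cohort table.
* **Synthetic phantom** — a deforming half-ellipsoid with the full
  crystal layout, affine systole (closed-form strain truth), scalable
  annular ring, ECG/pressure channels and Gaussian coordinate noise,
  standing in for animal recordings that are not publicly deposited.

Recordings are read and written as plain-text bundles
(`<stem>.header.json` + `<stem>.channels.csv`).

## Worked example

```r
library(rvkin)
lay <- crystal_layout()
ph  <- generate_phantom(phantom_config(seed = 1, noise_sd = 0.1,
                                       tra_ring_scale = sqrt(0.53)))
pa  <- analyze_pair(ph$baseline, ph$tra, lay)
pa$geometry
```

```
RV geometry at end-diastole (Baseline vs TRA)
      variable baseline     tra   delta
       taa_mm2   997.90  529.52 -468.38
        edv_ml   191.90  183.07   -8.83
 csa_basal_mm2  3817.39 3822.55    5.16
  roc_basal_mm    40.07   40.10    0.03
   csa_mid_mm2  2461.16 2461.03   -0.14
    roc_mid_mm    35.08   35.08    0.00
 csa_lower_mm2  1270.46 1269.71   -0.75
  roc_lower_mm    25.20   25.20   -0.01
Tricuspid annular area reduction: 46.9 %
```

The annular area falls from ~998 to ~530 mm² (the phantom's built-in
47 % ring-area reduction, recovered as 46.9 % under 0.1 mm coordinate
noise), the hull volume drops a few ml with the ring, and free-wall
CSA/ROC are untouched — the intervention acts on the annulus, not the
wall. End-systolic regional strains for the same run:

```r
round(pa$strain$baseline, 4)
```

```
         E_cc    E_ll   areal
basal -0.0777 -0.0547 -0.1327
mid   -0.0773 -0.0527 -0.1304
lower -0.0771 -0.0540 -0.1315
apex  -0.0772 -0.0613 -0.1386
```

The exact value for the phantom's circumferential systolic stretch of
0.92 is `E_cc = (0.92² − 1)/2 = −0.0768`; the measured regional means
sit within the coordinate-noise scatter of it. Negative = shortening.
Cohort tables across several pairs come from `build_report()`.

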