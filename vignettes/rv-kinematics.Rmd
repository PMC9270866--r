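---
title: "RV geometry and epicardial strain from sonomicrometry crystal arrays"
author: "rvkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RV geometry and epicardial strain from sonomicrometry crystal arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvkin)
```

## The measurement problem

Sonomicrometry tracks the 3D positions of small piezoelectric crystals
implanted on the beating heart, by time-of-flight of ultrasound pulses
between every crystal pair. A typical right-ventricular (RV) study
instruments 20 crystals — 6 in a ring around the tricuspid annulus, 13
on the free-wall epicardium along three circumferential parallels
(basal, mid, lower), and 1 at the apex — and records their
trajectories at 128 Hz together with left-ventricular (LV) pressure,
RV pressure, central venous pressure and ECG. Two states are acquired
with the same crystals: a Baseline and a post-intervention state,
here tricuspid ring annuloplasty (TRA), a prosthetic ring that
reduces the annular area.

From these channels the package computes, per state and per animal:

* **Cycle landmarks.** End-diastole (ED) is the R-wave peak on the
  ECG; end-systole (ES) is the time of maximum negative dP/dt of LV
  pressure. These are the standard sonomicrometry landmark
  definitions; the detector constants (moving-median detrend over
  600 ms, threshold at 60 % of the 98th-percentile amplitude, 200 ms
  refractory period, 5-sample dP/dt smoothing) are package
  conventions, all configurable. Two further phases that appear on
  strain timecourses, EIVC (end of isovolumic contraction, maximum
  positive dP/dt) and EIVR (end of isovolumic relaxation, first LVP
  recrossing of its ED value), are likewise conventions of this
  package, flagged as such, because no acquisition-level definition
  exists for them.
* **Beat averaging.** Four consecutive sinus beats are linearly
  resampled from ED to ED onto a fixed 0–100 % grid (101 points) and
  averaged pointwise, channels and coordinates alike. Averaging raw
  channels on the normalized grid (rather than averaging derived
  scalars per beat) is a deliberate choice: every downstream quantity
  is then computed once, from a single representative beat, and
  landmark phases are averaged in normalized time. The alternative —
  per-beat scalars, then averaging — gives the same first-order
  result for the smooth quantities involved and is not implemented.
* **Geometry.** Tricuspid annular area (TAA) as the shoelace area of
  the 6 annular crystals projected on their least-squares plane (the
  annulus is not planar, so the projection is part of the
  definition); RV volume as the convex hull of all 20 crystals in ml
  (a shape index, not a cavity volume — the crystals are epicardial);
  per-parallel cross-sectional area (CSA, chord-closed projected
  polygon) and radius of curvature (ROC, in-plane Kåsa circle fit
  with one Gauss–Newton refinement, exact on noise-free circles).
* **Strain.** Regional circumferential, longitudinal and areal
  Green–Lagrange strains on a triangulated, Loop-subdivided crystal
  mesh (next section).
* **Cohort statistics.** Paired t (the closed-form dependent-samples
  t), exact Wilcoxon signed-rank, and Shapiro–Wilk normality flags,
  in a two-state table mirroring the usual haemodynamics/geometry
  report layout.

## The strain model

The free-wall crystals are sparse (14 points), so strain is computed
on a smooth surface reconstructed from them:

1. **Base mesh.** Rows are zipped into triangle strips
   (annulus→basal→mid→lower) and an apex fan closes the surface; the
   mesh is a manifold disk whose single boundary is the annular ring.
   Connectivity is decided *from the layout alone* (the zipper
   advances whichever row's next vertex comes first in nominal
   circumferential phase). This matters: Baseline and TRA meshes must
   correspond face-by-face for interventional strain to be defined,
   and a geometry-dependent triangulation rule (e.g. comparing
   measured diagonal lengths) can flip near-tie diagonals between
   states. For evenly spread rows the phase rule *is* the
   shorter-diagonal choice.
2. **Loop subdivision.** The mesh is refined by Loop's scheme with
   the standard boundary modification: interior edge midpoints use
   the 3/8–3/8–1/8–1/8 mask, interior vertices the valence-`n` mask
   with `beta = (5/8 - (3/8 + cos(2*pi/n)/4)^2)/n`, boundary vertices
   the cubic-spline 1/8–3/4–1/8 mask, and boundary edge midpoints the
   plain average. The operator is linear in vertex positions and
   depends only on connectivity, so one sparse matrix `S` maps any
   frame's 20 crystal positions to the refined mesh. Reference (ED)
   and deformed frames are refined by the *same* `S`; the reference
   is also evaluated through `S` so that identical configurations
   give identically zero strain. Default level 2 (512 faces);
   regional means change by less than 0.005 strain between levels 2
   and 3 on smooth deformations.
3. **Per-face deformation gradient.** Each triangle carries an
   orthonormal tangent frame (first axis along its first edge). The
   in-plane edge matrices are then upper triangular and the 2×2
   deformation gradient `F = B A^-1` has a closed form with
   `det F > 0` for any non-degenerate pair. `E = (F'F - I)/2` is the
   Green–Lagrange tensor; it vanishes for rigid motions, making every
   strain output objective.
4. **Material directions.** The long axis runs from the annular
   centroid to the apex at the reference time. Per face,
   longitudinal = in-plane projection of the long axis,
   circumferential = its in-plane perpendicular (`n × l`). For a
   globally affine deformation `x -> A x + b` the computed
   directional strain equals `(|A d|^2 - 1)/2` exactly, at any
   subdivision level — this affine exactness is the package's
   primary correctness lever.
5. **Areal strain** is reported as `det F - 1 = dA/dA0 - 1`, the
   relative area change (0 = no change, −0.19 for isotropic in-plane
   contraction by 0.9).
6. **Aggregation.** Per-face values are summarized per region
   (basal/mid/lower/apex strips) as reference-area-weighted means ±
   SD; the unweighted estimator is also available. Faces are the
   native element of a piecewise-linear surface, so strain is
   per-face, not per-vertex.

Two reference conventions coexist, as in the underlying study design:
**cardiac strain** references each state to its own ED throughout the
cycle; **interventional strain** references TRA to Baseline at a
matched time point (ED or ES). Swapping the arguments of
interventional strain yields the inverse deformation; per face the
areal strains satisfy `(1 + a12)(1 + a21) = 1` exactly.

## The synthetic phantom

Animal recordings of this kind are not publicly deposited, so the
package ships a generator whose output has closed-form ground truth
for every downstream quantity. The phantom is a half-ellipsoid shell
(defaults a = b = 42 mm, c = 85 mm) carrying the 20-crystal layout,
with a 6-crystal annular ring of circumradius 19.58 mm at the base —
chosen so the hexagonal ring area is ~996 mm², the magnitude of a
dilated ovine tricuspid annulus. Systole is a time-varying affine map
`A(t) = diag(alpha, alpha, gamma)` with raised-cosine activation
rising from ED to ES (default ES at 40 % of the cycle) and relaxing
by 75 %; default systolic stretches are 0.92 circumferential and 0.95
longitudinal, i.e. mid-single-digit-percent strains. The TRA state
scales the ring by `sqrt(0.53)` in its plane (a 47 % area reduction)
and can additionally apply an arbitrary affine to all crystals. ECG
is a train of narrow Gaussian R spikes at cycle starts; LVP is a
raised-cosine pulse whose steepest descent falls exactly at the
configured ES phase (peak 87 mmHg by default, RVP 42, CVP 12, heart
rate 106/min). Coordinate noise is iid Gaussian per sample and axis;
rigid motions can be posed per state.

The affine deformation is deliberately *not* physiological: it is the
largest deformation class for which directional and areal strains
have exact closed forms, which turns every pipeline test into an
analytic comparison. Consequences to keep in mind:

* The phantom's parallels are closed loops spanning the full
  circumference, so the mesh is an exact disk; a real free wall
  covers only part of the circumference and the septal boundary is
  irregular.
* Homogeneous strain means regional means carry no spatial contrast;
  tests of regional *differences* are outside what the phantom can
  certify.
* ECG and pressure morphology are idealized; the landmark detector is
  validated for clean sinus rhythm, not for arrhythmia or drift
  (coordinate noise is modelled; channel noise is not).
* The convex hull of 20 points under-fills its generating
  half-ellipsoid by a sizeable, geometry-dependent margin (measured
  ~0.6× the closed-form ellipsoid volume at the default layout):
  hull "volume" is comparable across states and animals, not an
  absolute cavity measure.

## Numerical conventions worth knowing

* **Units** are fixed internally: mm, mmHg, s, ml (= mm³/1000);
  bundle headers may declare cm, converted on read. Bundles are a
  JSON header + CSV channel table written with 15 significant
  digits, so write∘read round-trips to better than 1e-9.
* **Timepoints** resolve as: `"ED"` = 0 % of the averaged cycle,
  `"ES"` = the averaged ES phase, or any numeric percent.
* **Degeneracies** error early and by name: collinear plane/circle
  fits, coplanar hulls, zero-area faces, inverted elements
  (`det F <= 0`), zero-variance paired tests.
* **Beat-averaging noise gain.** Linear interpolation between two
  samples shrinks iid noise variance by `(1-w)^2 + w^2`; the averaged
  beat records the per-grid-point gain
  `sqrt(mean_b[(1-w)^2 + w^2])`, so the sample-domain noise SD of an
  n-beat average is recovered as `residual SD / gain = sigma/sqrt(n)`.
  Noise-law checks use this estimator; comparing raw residuals
  against `sigma/2` directly would fold in a deterministic ~0.82
  interpolation factor.
* **Wilcoxon exact p** uses mid-ranks with zeros dropped and is
  computed by convolution over doubled (hence integer) ranks — exact
  under ties, unlike the reference implementation, which falls back
  to a normal approximation. Two-sided p is
  `2*min(P(W <= w), P(W >= w))`, capped at 1. The paired t is the
  closed form; Shapiro–Wilk is delegated to `stats::shapiro.test`
  (Royston's algorithm). Both tests are two-sided and no multiplicity
  correction is applied, matching the report conventions of paired
  two-state studies of this size.
* **"4 consecutive cycles"** means the first 4 usable cycles unless a
  start beat is given — a determinism choice.
* **Problem sizes.** Validation simulations in the test suite use
  3–5-cycle phantoms (around 350–500 samples), 100-phantom landmark
  sweeps, 200-draw noise-law studies and 500-cohort type-I-error
  studies at subdivision level 2; these sizes give Monte-Carlo error
  comfortably inside every asserted tolerance.

## A worked run

```{r example, eval = FALSE}
lay <- crystal_layout()
ph <- generate_phantom(phantom_config(seed = 1, noise_sd = 0.1,
                                      tra_ring_scale = sqrt(0.53)))
pa <- analyze_pair(ph$baseline, ph$tra, lay)
pa$geometry                 # TAA / EDV / CSA / ROC, Baseline vs TRA
pa$strain$baseline          # regional strain at end-systole
pa$interventional$ED        # TRA-vs-Baseline strain at end-diastole

cohort <- lapply(1:8, function(k) {
  phk <- generate_phantom(phantom_config(seed = k, noise_sd = 0.1,
                                         tra_ring_scale = sqrt(0.53)))
  analyze_pair(phk$baseline, phk$tra, lay, strain = FALSE)
})
build_report(cohort)
```

## Known limitations

Epicardial strain only (no transmural or fibre-direction components);
no arrhythmia handling beyond flagging unusable cycles; the hull
volume is a shape index; EIVR is undefined (NA) whenever LVP never
falls below its ED value within the beat; the phantom certifies
kinematic correctness, not physiological realism. The report layer
prints both t and Wilcoxon p-values rather than selecting one by the
normality flag, because selection rules vary between laboratories.
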