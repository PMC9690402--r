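---
title: "Quantifying comorbidity biomarkers from chest CT: methods and design"
author: "ctscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying comorbidity biomarkers from chest CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctscreen)
```

# Scope and data model

`ctscreen` turns a chest(-abdomen) CT volume plus anatomical label maps into
a panel of quantitative comorbidity biomarkers and a traffic-light report.
It deliberately begins where segmentation ends: lungs, liver, fat
compartments, vascular beds, vertebrae, calibration rods and nodules arrive
as an integer label map whose nonzero labels are bound to role names from a
closed registry (`roleRegistry()`). The package performs no segmentation,
registration or resampling — label maps must already be congruent with the
volume (spacing agreement within 10^-3 mm is enforced, and nothing is ever
resampled here, because silently regridding a segmentation changes the very
quantities being measured). Analysis runs on the native grid; whether
isotropic resampling before quantification would be preferable is an open
question we deliberately answer "no" at desk scale, since every quantity
below is computed through the physical voxel spacing.

Two S4 classes carry the data: `CTVolume` (HU voxels, spacing, origin) and
`MaskSet` (labelmap + role semantics). Every measurement is returned as a
`BiomarkerResult` whose status derives deterministically from the value and
the active reference range; a missing structure yields `not_evaluated`,
never zero — an abdomen outside the field of view must not masquerade as an
aortic calcium score of 0.

# Cardiovascular: per-compartment Agatston scoring

Calcified lesions are per-slice connected components (8-connectivity in
plane) of voxels at or above the detection threshold, intersected with
exactly one vascular compartment (coronary, thoracic or abdominal aorta).
Voxels inside a `bone_exclusion` mask are removed *before* component
labeling, so adjacent bone or dense foreign material cannot seed a false
positive. Components smaller than the minimum lesion area are dropped.
Each surviving component contributes `area_mm2 * w(peak HU)` with the
classical density weights (1: 130–199, 2: 200–299, 3: 300–399, 4: ≥ 400 HU);
a compartment's Agatston score sums its components and the volume score is
the physical volume of lesion voxels.

Numerical choices worth stating:

* **Per-slice scoring.** The density weights are defined per axial slice;
  3-D lesions exist only as groups of z-adjacent overlapping components and
  affect lesion *counts*, never scores. Raising the threshold can therefore
  split a 3-D lesion and increase the count even though score and calcified
  volume can only shrink — the monotonicity the tests assert is on score and
  volume.
* **Minimum lesion area 1 mm²** (the classical "three adjacent pixels"),
  configurable; **threshold 130 HU** for non-contrast scans. Contrast-enhanced
  studies are supported only through a user-raised threshold; no blood-pool
  adaptation is attempted.
* **No slice-thickness renormalization by default**; a thickness/3 mm factor
  is available but off, since published scores are most often reported
  unnormalized.
* CAC bands (0 / ≤10 / ≤100 / ≤400 / >400 → none…severe) and the statin
  texts are config data. The recommendation escalates to high-intensity
  statin therapy exactly at a score of 300. Aortic scores have no validated
  banding; they carry a configurable "high" flag only.

# Adipose tissue and liver

Fat planimetry is single-slice: the axial slice nearest the midpoint of the
L2 and L3 vertebral-body centroids. Per compartment, the area is the count
of pixels inside the fat window — [−190, −30] HU, inclusive on both ends
(the window is standard; inclusivity is our convention and a config key) —
times the pixel area. VFA/SFA are banded against an editable mean ± SD
population table (shipped values are placeholders to be replaced per
cohort: green within 1 SD, yellow within 2, red beyond); IMAT is reported
but not banded, since only visceral/subcutaneous fat carry an established
flagging convention.

Liver attenuation uses an automated ball ROI in the right hepatic lobe,
operationalized as: among liver voxels patient-right of the liver centroid,
take the interior point with maximal Euclidean distance to the mask
boundary, and average HU over the ball (default radius 10 mm) intersected
with the liver. If the deepest point is shallower than half the radius the
measurement is not evaluated rather than contaminated by boundary partial
volume. The fat conversion is the linear form `fat% = −0.58·HU + 38.2`
(clipped at 0, rounded to integer percent) with grades none/mild/moderate/
severe at 5/15/30%; slope, intercept and grade edges are config keys, and
the conversion refuses to run when the scan is flagged contrast-enhanced.

# Lung parenchyma

Over the joint lung mask: volume, mean lung density, and the emphysema
index as %LAA-950 (voxels below −950 HU) — the standard densitometric
threshold. GGO ([−800, −500) HU) and fibrosis ([−500, −200] HU) windows are
shipped but flagged *unvalidated* in the result provenance; they are
placeholders for texture-based methods that are out of scope. The
bronchiectasis index is pass-through only.

PRM classifies each voxel of a voxel-aligned inspiratory/expiratory pair:
emphysema (insp < −950, exp < −856), fSAD (insp ≥ −950, exp < −856), normal
(both above), uncharacterized (insp < −950, exp ≥ −856). The four fractions
partition the lung exactly. Deformable registration is upstream; congruence
is enforced.

Airway morphometry consumes an external measurement table
(`airway_id, Pi_mm, lumen_mm2, WA_mm2`). Pi10 is the standard √WA
regression `sqrt(WA) = a + b·Pi` evaluated at an internal perimeter of
10 mm; the result (mm) is reported in cm, matching how the metric's unit is
conventionally printed — reported Pi10 values in the 0.2–0.3 range only make
sense on that scale. Wall percentage is the per-airway mean of
`100·WA/(WA+lumen)`. At least two distinct perimeters are required.

# Nodules and Lung-RADS

Nodules are measured from masks (bounding-box extents per axis; long and
short axis from the axial slice of maximal area) or constructed from three
reported axis diameters, in which case the two largest serve as long/short
axes. The classification diameter is the mean of long and short axis. The
reported volume is the ellipsoid approximation `π/6·dx·dy·dz`, chosen
because it reproduces printed example volumes exactly; the voxel-count
volume is kept in provenance and agrees within 15% for spheres ≥ 4 mm at
≤ 0.5 mm voxels. Baseline solid Lung-RADS v1.1 bands apply (< 6 mm → 2,
6–8 → 3, 8–15 → 4A, ≥ 15 → 4B; no nodules → 1); the study category is the
maximum across nodules. Detection probability is pass-through. A plain
supra-threshold 3-D component finder (−300 HU, inside the lung mask) stands
in for an upstream detector on phantoms only.

# Bone: QCT calibration and T-scores

The trabecular compartment is extracted by eroding each labeled vertebral
body with a 3 mm physical ball — a geometric stand-in for a learned
cortical/trabecular separation that strips the cortical shell and surface
partial volume; bodies thinner than twice the margin are not evaluated.
Rod calibration fits `density = slope·HU + intercept` by least squares over
calibration rods of known hydroxyapatite density (≥ 2 distinct rods, else
fixed coefficients from config). The T-score uses a young-adult reference
of mean 178.5 and SD 27.5 mg/cm³ — back-solved from published worked
example pairs (85 mg/cm³ ↔ −3.4 and 52 mg/cm³ ↔ −4.6 imply SD = 33/1.2 =
27.5, mean = 85 + 3.4·27.5 = 178.5) because in-house reference tables are
never printed; both are config keys that a site should replace with its own
reference. Classification follows the WHO convention (T ≤ −2.5
osteoporosis, −2.5 < T < −1 osteopenia). The reported level is L1 when
measurable, else the lowest measured thoracolumbar level; absolute-BMD
banding is deliberately not applied, since the T-score is the clinical
anchor and absolute QCT bands would double-grade the same number.

# Reference ranges and the report

A `ReferenceRange` is a green interval inside a yellow interval; everything
else is red, boundaries belong to the greener band, and any finite value
maps to exactly one status. The "yellow = in between" convention is
qualitative in the source material, so per-biomarker yellow widths are
config values. Conclusions are template sentences keyed on category labels
(CAC band → statin sentence, Lung-RADS → follow-up interval, T-score class
→ osteoporosis sentence); all guideline wording lives in
`inst/extdata/config.yaml` because recommendations evolve faster than code.
The report is JSON-first (schema shipped in `inst/extdata/`), with text and
HTML renderings that are pure functions of the document; statuses are data,
colors are presentation.

`runStudy()` orchestrates the five analyzers as an in-process directed
acyclic graph: analyzers are independent given their inputs, so any
execution order consistent with the dependencies yields a byte-identical
report, and a failing analyzer degrades to a `not_evaluated` section with a
logged diagnostic instead of aborting the study.

# The phantom: what it emulates and what it does not

`phantomSpec()` describes a geometric chest-abdomen phantom — body ellipse,
subcutaneous fat ring, muscle band with fat islands, visceral fat disk,
liver sphere, lung ellipsoids, vertebrae with cortical shell and trabecular
core, vessels carrying plaques of prescribed area and peak HU,
hydroxyapatite rods, one nodule. Overlaps rasterize under a fixed
precedence (plaques > nodules > rods > vessels > organs > fat > body) so
every voxel has one deterministic label. The manifest records each expected
value, computed analytically or by the built-in brute-force voxel oracle
(the Agatston oracle is an independent implementation — iterative label
propagation rather than the analyzer's union-find — so the cross-check is a
genuine dual route). Additive Gaussian noise (seeded, volume only, applied
after the manifest) is the entire noise model.

Default study conditions used by the tests: a 96 × 96 × 84 grid at
1.5 × 1.5 × 2.5 mm (smaller 48³–64³ grids for repeated-seed suites), zero
noise unless a robustness property is under test (then σ = 10 HU over 20
seeds), emphysema emulated as a seeded 30% voxel class at −980 HU, rods at
0/100/200 mg/cm³ on the line density = HU − 10, trabecular bone at 110 HU
(an intentionally osteoporotic-range subject, so the bone pathway exercises
its red band end to end).

What the phantom does **not** emulate — and hence what passing tests do not
show about clinical data: anatomical shape variation, beam hardening and
scanner spectra, motion, contrast enhancement, partial-volume texture,
segmentation error (labels are exact by construction), and registration
error in the expiratory pair (it is voxel-aligned by construction). The
phantom validates the *quantification* given correct inputs; it cannot
validate the upstream models that produce those inputs.

# Known limitations

* NIfTI only; DICOM series must be converted upstream with the rescale
  equation applied (`applyRescale()` is provided for the arithmetic).
* Single-slice body composition; no volumetric fat, muscle quality or
  sarcopenia metrics.
* No per-coronary-artery breakdown, no mass score.
* GGO/fibrosis windows unvalidated; no texture classifier.
* Baseline solid Lung-RADS path only; part-solid/GGN tables are present in
  config but not exercised by default, and no follow-up/growth logic.
* No fracture detection or bone microarchitecture.
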