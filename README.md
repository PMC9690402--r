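# ctscreen

Opportunistic screening biomarkers from chest(-abdomen) CT.

A routine chest CT contains far more information than the question it was
ordered for. Given a CT volume in Hounsfield units (HU) and anatomical label
maps produced by an upstream segmenter, `ctscreen` quantifies the most common
pulmonary, cardiovascular, metabolic and musculoskeletal comorbidity
biomarkers, bands each value against reference ranges
(green / yellow / red), and assembles a structured, machine-readable report
with guideline-style recommendations. It is aimed at imaging researchers who
need a transparent, configurable desk-scale quantification back-end — the
segmentation/detection models themselves are out of scope and consumed as
label maps.

## What it computes

| Domain | Biomarkers | Method |
|---|---|---|
| Cardiovascular | CAC, TAC, AAC Agatston + volume scores | per-slice 8-connected components of voxels ≥ 130 HU per vascular compartment, bone-excluded; score = Σ area·w(peak), w = 1..4 for peaks 130–199 / 200–299 / 300–399 / ≥ 400 HU |
| Adipose / metabolic | VFA, SFA, IMAT (cm²); liver attenuation, fat %, steatosis grade | fat window [−190, −30] HU on the L2/L3 slice; automated 10 mm ball ROI in the right hepatic lobe; fat% = −0.58·HU + 38.2 |
| Lung parenchyma | lung volume, MLD, emphysema (%LAA-950), GGO and fibrosis indices; PRM (emphysema / fSAD / normal); Pi10, wall % | densitometric thresholds; PRM joint thresholding at −950 HU (insp) / −856 HU (exp); √WA = a + b·Pi regression evaluated at Pi = 10 mm |
| Pulmonary nodules | per-nodule diameters, ellipsoid volume π/6·dx·dy·dz, Lung-RADS | bounding-box extents; baseline solid bands 6 / 8 / 15 mm on the mean of long and short axes |
| Bone | trabecular HU, BMD (mg/cm³ HA), T-score, WHO class | 3 mm erosion of labeled vertebral bodies; rod calibration density = slope·HU + intercept; T = (BMD − 178.5)/27.5 |

A seeded synthetic phantom generator (`phantomSpec()` / `generatePhantom()`)
emits volume, label maps and a ground-truth manifest in which every expected
value is known analytically or from a built-in brute-force voxel oracle, so
the whole pipeline is testable without clinical data.

## Worked example

```r
library(ctscreen)

# the published worked examples
lungRADS(list(noduleFromDiameters(c(1.6, 3.5, 4.6))))$category  # "2"
noduleFromDiameters(c(1.6, 3.5, 4.6))$volume_mm3                # 13.4879
liverFatGrade(54)[c("fat_percent", "grade")]                    # 7, "mild"
bmdTscore(85, calibrationFromCoefficients(1, 0))[
  c("t_score", "classification")]                               # -3.4, "osteoporosis"

# a full synthetic study
ph  <- generatePhantom(phantomSpec(seed = 7))
doc <- runStudy(ph$volume, ph$masks)
cat(renderReport(doc, "txt"))
```

The tail of the rendered report:

```
Pulmonary nodules
-----------------
  Nodule count                          1        [yellow]
  Nodule 1 volume                70.68583 mm^3   [yellow] 4.5 mm x 6.0 mm x 5.0 mm
  Lung-RADS                             2        [yellow] Lung-RADS 2
  Conclusion: Pulmonary nodule with Lung-RADS 2. Follow-up in 12 months with CT.

Osteoporosis
------------
  Trabecular density                  110 HU     [red]
  BMD                                 100 mg/cm^3 [red] Level L1
  T-score                            -2.9        [red] osteoporosis
  Conclusion: Suspicion of osteoporosis with significantly reduced bone mineral density.
```

The phantom's vertebrae are generated at 110 HU trabecular density with a
calibration line density = HU − 10, so BMD = 100 mg/cm³ and
T = (100 − 178.5)/27.5 = −2.9: an osteoporotic subject by construction, which
the report flags red. `renderReport(doc, "json")` produces the
machine-readable twin (schema in `inst/extdata/report-schema.json`).

A command-line front-end lives at `inst/cli/ctscreen.R`:

```sh
Rscript inst/cli/ctscreen.R phantom --seed 7 --out ph7
Rscript inst/cli/ctscreen.R run --ct ph7/ct.nii.gz --masks ph7/masks.nii.gz \
        --roles ph7/semantics.yaml --out report7
```

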