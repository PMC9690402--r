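# Default analysis configuration. Every threshold an analyzer uses lives
# here so a site can adapt grading tables and guideline texts without
# touching code. Values flagged "placeholder" have no validated default
# and must be reviewed before clinical-style use.
adipose:
  fat_window_hu: [-190, -30]     # inclusive on both ends
  vfa:                           # population reference, mean +/- SD, cm^2
    mean: 150.0                  # placeholder cohort values; edit per site
    sd: 75.0
  sfa:
    mean: 200.0                  # placeholder cohort values; edit per site
    sd: 90.0
  imat_banded: false             # IMAT reported but not traffic-lighted
liver:
  roi_radius_mm: 10.0
  fat_slope: -0.58               # fat% = slope * HU + intercept
  fat_intercept: 38.2
  steatosis_thresholds: [5, 15, 30]   # none / mild / moderate / severe
  contrast_enhanced: false       # conversion invalid on contrast scans
cardio:
  threshold_hu: 130.0
  min_area_mm2: 1.0
  slice_thickness_norm: false    # optional thickness/3 mm factor
  cac_bands: [0, 10, 100, 400]   # none | minimal | mild | moderate | severe
  statin_consider_above: 100     # score > 100
  statin_high_intensity_at: 300  # score >= 300
  tac_high_above: 1000           # "high TAC"; no validated default
  aac_high_above: 1000           # "high AAC"; no validated default
lung:
  emphysema_hu: -950.0
  ggo_window_hu: [-800, -500]    # unvalidated placeholder window
  fibrosis_window_hu: [-500, -200]  # unvalidated placeholder window
  prm_insp_hu: -950.0
  prm_exp_hu: -856.0
  ei_green_max: 5.0              # emphysema index banding, %
  ei_yellow_max: 10.0
nodules:
  detect_threshold_hu: -300.0
  lungrads_solid_baseline_mm: [6, 8, 15]  # 2 | 3 | 4A | 4B band edges
bone:
  margin_mm: 3.0
  rod_densities: [0, 100, 200]   # mg/cm^3 HA, for calibration_rod_1..k
  reference_mean: 178.5          # young-adult trabecular BMD, mg/cm^3
  reference_sd: 27.5
  calibration: null              # optional fixed {slope, intercept}
templates:
  statin_consider: "Consider statin therapy."
  statin_high: "High-intensity statin therapy recommended (Agatston score >= 300)."
  cac_sentence: "%s CAC."
  vessel_high: "High %s with high risk for future cardiac events."
  fat_abnormal: "Measurement of visceral and/or subcutaneous fat outside the range of standard deviation."
  fat_normal: "Measurement of visceral and/or subcutaneous fat areas are normal."
  steatosis: "%s steatosis."
  steatosis_none: "No CT evidence of hepatic steatosis."
  nodule_found: "Pulmonary nodule with Lung-RADS %s."
  nodule_none: "No nodule detected."
  lungrads_followup:
    "1": "Continue annual screening with low-dose CT in 12 months."
    "2": "Follow-up in 12 months with CT."
    "3": "Follow-up low-dose CT in 6 months."
    "4A": "Follow-up low-dose CT in 3 months; PET/CT may be considered."
    "4B": "Chest CT with or without contrast, PET/CT and/or tissue sampling."
  emphysema_none: "No emphysema."
  emphysema_mild: "Mild to moderate emphysema."
  emphysema_severe: "Severe emphysema."
  wall_thickening: "Possible bronchial wall thickening."
  bone_osteoporosis: "Suspicion of osteoporosis with significantly reduced bone mineral density."
  bone_osteopenia: "Osteopenia with reduced bone mineral density."
  bone_normal: "Bone mineral density within the normal range."
  all_normal: "Values within the normal range."
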