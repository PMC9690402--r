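# Closed registry of anatomical role names for MaskSet semantics.
# Exact names plus parameterized families (vertebra levels, numbered
# calibration rods and nodules). Unknown roles are rejected at load.
version: 1
exact:
  - lung_left
  - lung_right
  - liver
  - visceral_compartment
  - subcutaneous_compartment
  - intermuscular_compartment
  - coronary
  - thoracic_aorta
  - abdominal_aorta
  - bone_exclusion
vertebra_levels:
  - T1
  - T2
  - T3
  - T4
  - T5
  - T6
  - T7
  - T8
  - T9
  - T10
  - T11
  - T12
  - L1
  - L2
  - L3
  - L4
  - L5
numbered_prefixes:
  - calibration_rod_
  - nodule_
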