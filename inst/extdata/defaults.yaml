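# Package-wide default parameters. Every value here is a documented default
# of this implementation and can be overridden by the caller.

# Specific tension converting PCSA (cm^2) to maximal force (N); applied
# uniformly to all fascicles. Set near the top of the published 46-100
# N/cm^2 range because the reduced fascicle set stands in for a much larger
# architecture: each fascicle carries its whole group's demand.
specific_tension: 90.0

# Whether the shipped PCSA table is interpreted per body side (the bilateral
# model instantiates one fascicle set per side at these values).
pcsa_per_side: true

# Linear body-fat regression on BMI, per sex. fat_fraction = slope*bmi + intercept,
# clamped to [0, 0.75]. Stand-in coefficients chosen to give ~25% fat for a
# BMI-20 female and ~21% for a BMI-24.7 male, consistent with adult norms.
fat_regression:
  female: {slope: 0.012, intercept: 0.020}
  male:   {slope: 0.012, intercept: -0.086}
fat_bmi_window: [13.0, 45.0]

# Length-mass-fat strength scaling: scale = (lean/lean_ref)^a / (stature/stature_ref)^b
strength_scaling:
  lean_mass_exponent: 1.0
  stature_exponent: 1.0

# Anchor subject for strength scaling.
reference_subject:
  sex: male
  stature: 1.75
  mass: 75.0
  age: 30.0

# Lumbar rhythm: share of the total trunk-pelvis rotation taken by each
# intervertebral joint, cranial to caudal (T12-L1, L1-L2, L2-L3, L3-L4,
# L4-L5, L5-S1). Each plane sums to exactly 1. Flexion share grows caudally;
# axial rotation is close to uniform.
lumbar_rhythm:
  flexion: [0.08, 0.12, 0.15, 0.18, 0.22, 0.25]
  lateral: [0.15, 0.20, 0.20, 0.20, 0.15, 0.10]
  axial:   [0.17, 0.17, 0.17, 0.17, 0.16, 0.16]

# Split of the erector spinae PCSA (one Table row) over its four fascicles.
erector_spinae_split:
  iliocostalis_pars_thoracis: 0.30
  longissimus_pars_thoracis: 0.30
  iliocostalis_pars_lumborum: 0.20
  longissimus_pars_lumborum: 0.20

# EMG electrode site -> fascicle mapping (sides handled automatically).
emg_site_mapping:
  multifidus: [multifidus, rotatores]
  lumbar_erector_spinae: [iliocostalis_pars_lumborum, longissimus_pars_lumborum]
  thoracic_erector_spinae: [iliocostalis_pars_thoracis, longissimus_pars_thoracis]
  external_oblique: [external_oblique]
  internal_oblique: [internal_oblique]
  rectus_abdominis: [rectus_abdominis]

# EMG processing
emg:
  bandpass: [30.0, 450.0]
  envelope_cutoff: 3.0
  filter_order: 2
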