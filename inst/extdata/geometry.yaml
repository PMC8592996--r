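# Model geometry. All lengths are fractions of subject stature unless a key
# ends in _m (absolute metres). Coordinates: right-handed, x anterior,
# y to the subject's left, z superior; origin at the L5-S1 joint centre;
# anchors on the right side are mirrored (y -> -y).

segments:
  lumbar_total_length: 0.108      # L5-S1 joint to T12-L1 joint, split equally over 5 vertebrae
  thorax_length: 0.250            # T12-L1 joint to shoulder line
  head_com_above_thorax: 0.080    # head+neck COM above the shoulder line
  shoulder_half_width: 0.115
  thorax_com: {x: 0.030, z_frac_of_length: 0.45}   # relative to T12-L1 joint
  lumbar_com: {x: 0.012}          # each vertebra, at its mid-height
  head_com: {x: 0.010}

# Arm mass placement along the shoulder -> hand line (fractions of that line).
arm_com_fractions:
  upper_arms: 0.20
  lower_arms: 0.55
  hands: 0.95

# Fascicle anchor points, one entry per side (left listed; right mirrored).
# inferior anchors sit on the pelvis, superior anchors on the named segment.
# Coordinates are stature fractions in the segment's neutral frame, z
# relative to the L5-S1 joint for pelvis/lumbar anchors and to the T12-L1
# joint for thorax anchors.
fascicles:
  # Superficial multifidus: one fascicle per lumbar level (caudal levels
  # carry a larger share), fibres running caudolaterally from a medial
  # superior anchor. Carries 55% of the multifidus PCSA.
  multifidus:
    follow_spine: true
    group: local
    source_fraction: 0.55
    levels: {L1: 0.12, L2: 0.16, L3: 0.20, L4: 0.24, L5: 0.28}
    inferior: {x: -0.0257, y: 0.0200, z: -0.0170}
    superior: {x: -0.0257, y: 0.0060}     # z: mid-height of the superior vertebra
  # Deep segmental fibres (rotatores / deep multifidus): one strongly
  # oblique one-joint fascicle per intervertebral joint, carrying the
  # remaining 45% of the multifidus PCSA. These give each joint its own
  # differential moment capability in all three planes.
  rotatores:
    group: local
    source_fraction: 0.45
    one_level: true
    levels: {L5: 0.22, L4: 0.20, L3: 0.18, L2: 0.15, L1: 0.13, thorax: 0.12}
    inferior: {x: -0.0300, y: 0.0230, z: -0.0110}
    superior: {x: -0.0300, y: 0.0030}
  longissimus_pars_lumborum:
    follow_spine: true
    group: local
    superior_segment: L1
    inferior: {x: -0.0290, y: 0.0170, z: -0.0170}
    superior: {x: -0.0290, y: 0.0170}
  iliocostalis_pars_lumborum:
    follow_spine: true
    group: local
    superior_segment: L2
    inferior: {x: -0.0315, y: 0.0260, z: -0.0200}
    superior: {x: -0.0315, y: 0.0260}
  quadratus_lumborum:
    follow_spine: true
    group: local
    superior_segment: L1
    inferior: {x: -0.0110, y: 0.0430, z: -0.0110}
    superior: {x: -0.0110, y: 0.0370}
  psoas_major:
    follow_spine: true
    group: local
    superior_segment: L1
    inferior: {x: 0.0110, y: 0.0230, z: -0.0290}
    superior: {x: 0.0140, y: 0.0260}
  iliocostalis_pars_thoracis:
    follow_spine: true
    group: global
    superior_segment: thorax
    inferior: {x: -0.0315, y: 0.0290, z: -0.0170}
    superior: {x: -0.0340, y: 0.0310, z: 0.0860}
  longissimus_pars_thoracis:
    follow_spine: true
    group: global
    superior_segment: thorax
    inferior: {x: -0.0290, y: 0.0170, z: -0.0170}
    superior: {x: -0.0315, y: 0.0200, z: 0.0860}
  rectus_abdominis:
    group: global
    superior_segment: thorax
    inferior: {x: 0.0510, y: 0.0200, z: -0.0290}
    superior: {x: 0.0570, y: 0.0200, z: 0.0460}
  # The oblique sheets fan into an anterior (rotator) and a lateral
  # (flexor) sub-fascicle each; the lateral fibres keep their moment
  # capability when the trunk is twisted or bent.
  external_oblique:
    group: global
    fans:
      anterior:
        fraction: 0.5
        superior_segment: thorax
        inferior: {x: 0.0460, y: 0.0110, z: -0.0260}
        superior: {x: 0.0170, y: 0.0600, z: 0.0290}
      lateral:
        fraction: 0.5
        superior_segment: thorax
        inferior: {x: 0.0060, y: 0.0690, z: -0.0230}
        superior: {x: 0.0000, y: 0.0630, z: 0.0290}
  internal_oblique:
    group: global
    fans:
      anterior:
        fraction: 0.5
        superior_segment: thorax
        inferior: {x: 0.0260, y: 0.0570, z: -0.0170}
        superior: {x: 0.0540, y: 0.0110, z: 0.0230}
      lateral:
        fraction: 0.5
        superior_segment: thorax
        inferior: {x: 0.0030, y: 0.0660, z: -0.0170}
        superior: {x: 0.0000, y: 0.0600, z: 0.0230}

# Intra-abdominal pressure actuator: extension moment = p * area * lever at
# every lumbar joint, p in [0, max_pressure_kpa].
iap:
  max_pressure_kpa: 26.6
  effective_area_frac: 0.0065     # m^2 per stature^2 (0.020 m^2 at 1.75 m)
  lever_arm_frac: 0.0400          # m per stature (0.07 m at 1.75 m)

# Linear intervertebral stiffness, N*m/deg per plane (flexion, lateral,
# axial), representing the disc and ligamentous resistance at each joint.
# Values are at the low end of published segmental bending stiffness; axial
# resistance is left to the musculature.
joint_stiffness: {flexion: 1.5, lateral: 1.0, axial: 0.0}
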