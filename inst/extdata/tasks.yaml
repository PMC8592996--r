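# The twelve static load-handling tasks. Posture templates are qualitative
# task descriptions made quantitative here; every angle (deg) and offset
# (fraction of stature) is an overridable default of this implementation.
#
# trunk_*: trunk-pelvis rotation (flexion +forward, lateral +right, axial
# +left / right-hand rule about the superior axis, so a right twist is
# negative). pelvis_flexion: forward pelvis/hip inclination. Hand offsets are
# in the pelvis frame: anterior x, lateral y (left +), height classes are
# fractions of stature above the floor.

hand_heights:
  knee: 0.28
  thigh: 0.42
  hip: 0.55
  chest: 0.70
  shoulder: 0.82
  head: 0.93

l5s1_height: 0.600   # L5-S1 joint height above the floor, fraction of stature

tasks:
  - id: T1
    label: relaxed upright standing
    load_kg: 0.0
    load_type: none
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 0.0
    arm_abduction: 0.0
    hand_height: thigh
    hand_anterior: 0.02
    hand_lateral: 0.10
    elbows_extended: false
  - id: T2
    label: full upper-body flexion, straight knees, no load
    load_kg: 0.0
    load_type: none
    unilateral: false
    trunk_flexion: 50.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 40.0
    arm_elevation: 0.0
    arm_abduction: 0.0
    hand_height: knee
    hand_anterior: 0.20
    hand_lateral: 0.10
    elbows_extended: true
  - id: T3
    label: two 5 kg dumbbells, arms close to the trunk, thigh height
    load_kg: 10.0
    load_type: dumbbells
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 0.0
    arm_abduction: 0.0
    hand_height: thigh
    hand_anterior: 0.02
    hand_lateral: 0.12
    elbows_extended: false
  - id: T4
    label: two 5 kg dumbbells, arms abducted 45 deg, hip height
    load_kg: 10.0
    load_type: dumbbells
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 0.0
    arm_abduction: 45.0
    hand_height: hip
    hand_anterior: 0.0
    hand_lateral: 0.28
    elbows_extended: false
  - id: T5
    label: two 5 kg dumbbells, arms abducted 90 deg, shoulder height
    load_kg: 10.0
    load_type: dumbbells
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 0.0
    arm_abduction: 90.0
    hand_height: shoulder
    hand_anterior: 0.0
    hand_lateral: 0.40
    elbows_extended: true
  - id: T6
    label: 10 kg box in front of and close to the body, hip height
    load_kg: 10.0
    load_type: box
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 20.0
    arm_abduction: 0.0
    hand_height: hip
    hand_anterior: 0.16
    hand_lateral: 0.10
    elbows_extended: false
  - id: T7
    label: 10 kg box in front of and close to the body, chest height
    load_kg: 10.0
    load_type: box
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 40.0
    arm_abduction: 0.0
    hand_height: chest
    hand_anterior: 0.16
    hand_lateral: 0.10
    elbows_extended: false
  - id: T8
    label: 10 kg box in front of and close to the body, head height
    load_kg: 10.0
    load_type: box
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 70.0
    arm_abduction: 0.0
    hand_height: head
    hand_anterior: 0.16
    hand_lateral: 0.10
    elbows_extended: false
  - id: T9
    label: 10 kg box in front of the body, chest height, extended elbows
    load_kg: 10.0
    load_type: box
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 60.0
    arm_abduction: 0.0
    hand_height: chest
    hand_anterior: 0.30
    hand_lateral: 0.10
    elbows_extended: true
  - id: T10
    label: 10 kg box, flexed back, extended knees
    load_kg: 10.0
    load_type: box
    unilateral: false
    trunk_flexion: 35.0
    trunk_lateral: 0.0
    trunk_axial: 0.0
    pelvis_flexion: 40.0
    arm_elevation: 0.0
    arm_abduction: 0.0
    hand_height: knee
    hand_anterior: 0.25
    hand_lateral: 0.10
    elbows_extended: true
  - id: T11
    label: 10 kg box held in one hand on the favoured (right) side
    load_kg: 10.0
    load_type: box
    unilateral: true
    unilateral_side: right
    trunk_flexion: 0.0
    trunk_lateral: -5.0
    trunk_axial: 0.0
    pelvis_flexion: 0.0
    arm_elevation: 0.0
    arm_abduction: 10.0
    hand_height: hip
    hand_anterior: 0.10
    hand_lateral: -0.14
    elbows_extended: false
  - id: T12
    label: 10 kg box in front of the body, trunk twisted to the right
    load_kg: 10.0
    load_type: box
    unilateral: false
    trunk_flexion: 0.0
    trunk_lateral: 0.0
    trunk_axial: -10.0
    pelvis_axial: -35.0
    pelvis_flexion: 0.0
    arm_elevation: 20.0
    arm_abduction: 0.0
    hand_height: hip
    hand_anterior: 0.16
    hand_lateral: 0.10
    elbows_extended: false
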