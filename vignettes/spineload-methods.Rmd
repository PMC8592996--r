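---
title: "Model and methods behind spineload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind spineload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spineload)
```

`spineload` estimates lumbosacral (L5-S1) compression and shear during
static manual-material-handling holds with a simplified, fully inspectable
musculoskeletal trunk model. This vignette is the package's own account of
that model: what is computed, which assumptions it rests on, which
parameters matter, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open.

## The mechanical model

**Rigid bodies and joints.** The trunk is a chain of seven rigid bodies —
pelvis, L5…L1, and a rigid thorax — connected by six 3-DoF spherical
joints with fixed centres of rotation (T12-L1 down to L5-S1). The head is
a point mass carried by the thorax; each arm is three point masses (upper
arm, forearm, hand) placed along the shoulder-to-hand line, so arm posture
enters only through hand placement. Segment lengths are fixed fractions of
stature; segment masses come from the variant's mass-fraction table, with
the `lumbar` row split equally over the five lumbar vertebrae (an
interpretation: the table does not subdivide it). Coordinates are
right-handed with x anterior, y to the subject's left, z superior; angles
are degrees at every interface.

**Posture.** A posture is a pelvis orientation plus a trunk-pelvis
rotation (flexion, lateral bend, axial rotation; intrinsic y-x-z
sequence). The trunk-pelvis rotation is distributed over the six joints by
a lumbar rhythm: per-plane shares that are nonnegative and sum to exactly
one, so per-plane joint rotations reconstruct the total identically. The
shipped rhythm grows caudally in flexion and is near-uniform in axial
rotation; it is a documented default, not a measured quantity, and every
analysis function accepts explicit coefficients.

**Muscles.** Ten muscle groups are modelled bilaterally as
piecewise-straight paths of segment-anchored points. Spine-following
paths (erector spinae, multifidus, quadratus lumborum, psoas) carry one
via point per intermediate vertebra: without them, a straight
pelvis-to-thorax chord loses its extension moment arm at mid-lumbar joints
as soon as the spine flexes substantially, which is geometrically wrong
and makes flexed tasks unsolvable. Two further architectural features
turned out to be load-bearing:

* *Deep segmental fascicles.* Demands grow caudally while polyarticular
  muscles produce nearly equal moments at every joint they cross, so a
  model with only polyarticular fascicles cannot independently set the
  moment difference between adjacent joints. The deep multifidus /
  rotatores layer — one strongly oblique, one-joint fascicle per
  intervertebral joint, carrying 45 % of the multifidus PCSA — provides
  exactly that differential capability in all three planes.
* *Fanned obliques.* The abdominal oblique sheets are split into an
  anterior (rotator) and a lateral (flexor) sub-fascicle each. A single
  oblique chord loses its axial-rotation moment arm in twisted postures;
  the fan keeps both functions represented.

Moment arms are geometric: the row of fascicle *i* at joint *j* is
`(upper_point - joint_centre) x unit_line` of the straight span crossing
the joint. They are verified in the test suite against a tendon-excursion
oracle (finite difference of path length with respect to each joint
angle).

**Strengths.** `N_i = PCSA_i x sigma x s`. The PCSA tables are shipped
verbatim per model variant and interpreted per body side. The specific
tension `sigma` defaults to 90 N/cm² — the upper half of the published
46–100 N/cm² range — because each fascicle of this reduced set stands in
for many fascicles of a full architecture; it is a single configurable
scalar, and only force ratios and load sums are anchored to the tables.
The subject scale `s` is the length-mass-fat law
`(lean/lean_ref)^a / (stature/stature_ref)^b` with default exponents
a = b = 1 and a 75 kg, 1.75 m male reference; only its identity and
homogeneity contracts are asserted, since the source law's constants are
not published. Body fat comes from a per-sex linear regression on BMI
(documented stand-in coefficients, clamped validity window [13, 45]
kg/m²).

**Passive moments and IAP.** Intervertebral joints resist rotation
linearly; the shipped stiffness is flexion 1.5, lateral 1.0, axial 0.0
N·m/deg. A zero default in all planes was tried first and rejected:
without any passive bending resistance the weakest variant
(female-specific) cannot satisfy three-component equilibrium at the
thoracolumbar junction in the deep stoop task, and the published model
family this package simplifies does include linear joint stiffness.
Axial resistance is deliberately left to the musculature. Intra-abdominal
pressure is a bounded, zero-cost actuator: a pressure p in [0, 26.6 kPa]
produces the extension moment `p x area x lever` at every joint
(defaults: 0.020 m² and 0.07 m at 1.75 m stature, scaling with stature).
Its direct axial unloading force on the joint reaction is not modelled —
a known simplification that biases compression slightly upward in
IAP-saturated tasks.

## Recruitment

At a posed, static configuration the net external moment at each joint
(gravity of all superincumbent bodies plus hand loads) must be balanced by
muscles, IAP and passive moments, component-wise at all six joints
(18 equality constraints). Redundancy is resolved by minimizing the sum of
cubed muscle stresses subject to force bounds — a strictly convex
objective over linear constraints, so the optimum is unique whenever any
muscle is active and no tie-breaking is needed.

The solver works in activity variables (`a_i = f_i/N_i`): an augmented
Lagrangian with bound-constrained L-BFGS-B inner solves, followed by an
active-set Newton polish on the KKT system that drives the equality
residual to machine precision. Tolerances: constraint 1e-8 relative to
`max(1, |demand|)` per joint (typical achieved residuals are 1e-12 to
1e-10 N·m), optimality checked in the tests against closed forms
(two-muscle solutions satisfy `f_i ∝ N_i^{3/2} r_i^{1/2}`) and an
exhaustive grid oracle. Infeasible demand is certified by a
bound-constrained least-squares minimization of the violation and reported
with the most violated joint and plane; infeasible battery rows are
flagged, never dropped.

Ground reaction forces are deliberately *not* a solver input: in a static
task the bottom-up path is redundant, so the vertical GRF sum is used only
as a consistency check against the supported weight.

## Tasks and postures

The twelve tasks are qualitative descriptions made quantitative in an
editable config: T1 upright; T2 full flexion (pelvis 40° + lumbar 50°,
90° total); T3–T5 dumbbell holds at three arm positions; T6–T8 box holds
at hip/chest/head height close to the body; T9 extended-elbow chest hold;
T10 stoop (pelvis 40° + lumbar 35°, box at knee height); T11 one-handed
hold on the right with a small leftward lean; T12 box hold with the trunk
twisted 45° to the right. For T12 the twist is split pelvis −35° / lumbar
−10°: the lumbar spine's axial range is anatomically small, and at larger
lumbar twist shares the oblique chords lose their rotation moment arms and
the hold becomes mechanically infeasible for any admissible recruitment.
Hand targets are placed at height classes (fractions of stature above the
floor) and follow the total axial rotation. Every angle and offset is a
default, not a claim about the original recordings.

Because gravity is vertical and arm masses lie on the shoulder-hand line,
box holds at different heights with the same horizontal reach produce
identical joint moments in this model — height classes differentiate
tasks only through reach and arm placement. Real holds differ more; this
is a consequence of the static point-mass arm model.

## EMG pipeline

Raw EMG (≥1 kHz) is band-passed 30–450 Hz, full-wave rectified, low-passed
at 3 Hz (all filters zero-lag 2nd-order Butterworth, applied
forward-backward, so the gain at a low-pass cutoff is 0.5), and divided by
the per-channel MVC peak — the maximum of the identically processed MVC
trials. Predicted site activities are the mean `force/strength` of the
fascicles mapped under each of the twelve electrode sites; correlations
between measured and predicted activities are computed across the twelve
task means per site, not across time samples. Cross-talk is not modelled.

## Synthetic data: what it emulates, what it does not

The generator replaces the study's recordings, which are not deposited.
Subjects are sampled from per-sex truncated normals (±3 sd) matching the
study's demographic means and sds, with stature and mass drawn
independently (real covariation is ignored; the fat-regression window is
wide enough to absorb the resulting BMI extremes). A trial solves the
model to obtain ground-truth forces, activities and loads, then emits a
3-s hold padded by 0.5 s on each side (the padding absorbs zero-lag filter
edge transients in downstream processing): quasi-constant posture channels
(constant plus tremor), GRFs whose vertical sum is the supported weight
plus sensor noise, and per-site raw EMG as a 30–450 Hz Gaussian carrier
scaled so its RMS equals `activity x MVC amplitude`, plus additive noise
proportional to the clean-signal RMS. MVC trials are generated at
activity 1. All randomness flows from one seed through a documented
substream splitter, so trials are bit-reproducible.

What passing the closure tests shows: the estimation pipeline exactly
inverts the generator's forward model — filtering, hold averaging, posture
reconstruction, recruitment and load extraction introduce no systematic
error, and the EMG chain recovers known activity modulations at realistic
noise. What it does not show: fidelity to real recordings. The generator
has no soft-tissue artifact, no marker occlusion, no postural drift, no
physiological EMG spectrum or cross-talk, and its ground truth comes from
the same model family that the pipeline fits. Sites whose predicted
activity is constant across all tasks (rectus abdominis in some
batteries) have no defined Pearson correlation and are excluded from
recovery summaries, with the count of defined sites reported.

## Numerical choices and degenerate inputs

* Rotation decomposition is intrinsic flexion → lateral → axial; at
  gimbal lock (lateral = ±90°) the flexion/axial split is conventional.
* Rhythm coefficients failing the sum-to-one invariant, non-orthonormal
  frames, out-of-window BMI, zero MVC peaks, zero-variance correlation
  input, and unknown variants/tasks/sites are all rejected explicitly.
* The solver's uniqueness argument fails only in the measure-zero case of
  a zero-demand problem, where the zero solution is returned.
* Percent differences are reported under both denominator conventions,
  labelled, because aggregate percentages are ambiguous otherwise; no
  multiple-testing correction is applied, and this is noted in the report.

## Problem sizes

The shipped analyses use 10 + 10 subjects x 3 variants x 12 tasks
(360 recruitment solves, ~57 fascicle variables and 18 constraints each),
100 random oracle problems with 2–5 muscles, and 3-s synthetic trials at
200/1000/2000 Hz. These sizes match the study design they emulate and keep
the whole suite comfortably fast on a single CPU.

## Known limitations

Beyond the generator's idealizations: no force-length-velocity muscle
behaviour (static holds only), no ligaments or facet joints, fixed centres
of rotation, no wrapping surfaces (via points are rigidly segment-fixed),
moment arms are not sex-specific, the IAP mechanism is a moment actuator
rather than a pressurized volume, and flexed-task compressions are likely
overestimated because passive load-sharing in deep flexion is only crudely
represented by the linear stiffness. Subject-level results of the original
study are not reproducible here and are not claimed: its raw data are not
deposited, so all paper-anchored checks are table arithmetic, design
counts and direction-level effects.
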