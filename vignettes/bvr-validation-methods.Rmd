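---
title: "Methods: synthetic validation of model-based BVR knee tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic validation of model-based BVR knee tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvrkin)
```

## The problem

Biplane videoradiography (BVR) reconstructs 3D bone motion from two
synchronized X-ray video views. Two tracking routes exist: *marker-based*
tracking triangulates implanted radio-opaque beads and rigidly registers them
to their CT-known positions (the gold standard, sub-0.1 mm), and
*model-based* tracking registers a CT-derived bone model directly to the
radiographs, which is what can actually be used in patients. Validating
model-based tracking for a given system geometry means quantifying, per
degree of freedom (DOF), the accuracy (mean absolute difference, MAD ± SD),
bias (mean signed difference), and precision (Bland–Altman limits of
agreement, LoA) of model-based against marker-based kinematics.

The canonical experimental design uses cadaveric knees frozen rigid at a
flexed angle: because the tibiofemoral joint cannot move, *any* apparent
relative motion between femur and tibia is tracking error. `bvrkin`
implements that entire validation as a reproducible synthetic pipeline:
a scene generator stands in for the cadaver lab, and every downstream stage
(triangulation, rigid registration, quaternion filtering, Euler
decomposition, agreement statistics) is real, tested code.

## What the generator emulates

The defaults are the study conditions the pipeline is meant to exercise:

* **Geometry** — two pinhole-style X-ray views with a source-to-image
  distance of 1850 mm, a 55° separation angle between the beams, 250 Hz
  frame rate, and 400 × 400 mm detectors at 0.25 mm/pixel. The beams lie in
  the horizontal plane and intersect at the lab origin; the shared field of
  view at the isocentre is roughly 240 mm across.
* **Specimens** — three presets with soft-tissue volumes of 3038, 1203 and
  3964 cm³. Each bone carries 6–8 beads sampled under non-degeneracy
  constraints (pairwise distance > 5 mm, out-of-plane RMS > 1 mm) and
  anatomical landmarks near realistic positions. The frozen tibiofemoral
  pose is built from a flexion angle drawn in 20–55°, small out-of-plane
  angles (SD 1.5°), and a joint offset of about 40 mm along the femoral long
  axis.
* **Motions** — hop trials translate horizontally at 0.9 ± 0.3 m/s for
  0.3 s (75 frames); drop trials fall vertically at 1.8 ± 0.4 m/s for
  0.04 s (10 frames, the trial ending at ground contact). The per-trial
  speed is drawn once and held constant; a 2 Hz transverse wobble and a slow
  orientation wander (≤ 2 mm and ≤ 2° per m/s of speed) emulate handheld
  manipulation and vanish for a stationary trial. Ground contact is modelled
  as trajectory termination; no impact dynamics.
* **Bead observations** — perspective projection onto each detector with
  Gaussian pixel noise (default SD 0.5 px). Visibility is decided on the
  noise-free projection; beads outside the detector or behind a source are
  never given coordinates.
* **Model-based tracking** — the 2D–3D registration algorithm itself is out
  of scope. Its error is *emulated*: each frame's true pose is perturbed in
  the bone frame by a rotation about a uniformly random axis with angle
  |N(0, 0.45°)| and by N(0, 0.40 mm) per translation axis. Frames partially
  out of the field of view — and, independently, a random 5% of frames —
  receive 4× noise, emulating the edge-of-field outliers that dominate real
  Bland–Altman tails. The 4× multiplier is a free choice (no published
  quantification exists); a per-specimen `noise_scale` is exposed and
  defaults to 1.
* **Default demo** — 33 trials (7 hop + 4 drop per specimen), mirroring the
  scale of a real validation session.

The default noise SDs sit in the lower half of the plausible 0.4–0.6 band on
purpose: joint-level differences compound *two* bones' rotation and
translation noise, plus a lever-arm term (the ~40–80 mm offset between the
femoral and tibial origins converts 0.45° of rotation noise into ~0.3 mm of
translation difference). With 0.45°/0.40 mm per bone and the outlier
mixture, the pooled joint-level MAD lands at roughly 0.4° for rotations and
0.7 mm for translations — the order of magnitude real systems report.

What the generator does **not** emulate: X-ray physics (scatter, beam
hardening, motion blur), CT segmentation, image-based bead detection,
soft-tissue deformation (real tissues were frozen), and any temporal
correlation in model-tracking error. Passing tests therefore demonstrate
that the *pipeline* is correct and that its statistics behave as designed —
not that a particular physical system achieves a particular accuracy.

## The kinematics chain

Marker tracking triangulates each bead visible in both views
(least-squares intersection of the two back-projected rays; rays less than
1° apart are rejected as ill-conditioned) and registers the CT bead cloud
onto the triangulated cloud with the Kabsch SVD solution
(determinant-corrected to exclude reflections). A frame needs at least 3
beads per bone; a frame enters the analysis only when *both* bones have
marker fits.

Anatomical frames follow a fixed landmark convention (X through the
epicondyles/plateau points, Z along the shaft superior-positive,
Y = Z × X, origin midway between the paired landmarks). The reference this
construction would normally cite is not reproduced here, so the convention
is simply documented and fixed. Per-DOF Euler statistics are *not* exactly
invariant to this choice — rotating the anatomical axes redistributes error
between DOFs — but the rotation-angle magnitude of the per-frame
marker-vs-model difference transform is exactly invariant (conjugation
preserves the angle), and a property test asserts that plus approximate
per-DOF stability under small axis perturbations.

Joint kinematics are the tibia expressed in the femoral anatomical frame,
`femur_acs ∘ femur_T⁻¹ ∘ tibia_T ∘ tibia_acs⁻¹`, decomposed in an X-Y-Z
Euler sequence as R = Rx(FE)·Ry(AA)·Rz(IE); translations are read on the
femoral anatomical axes (ML = X, AP = Y, IS = Z). Gimbal proximity
(|cos AA| < 1e-6) raises an error rather than returning silently wrong
angles. Angles are radians internally and degrees at every interface.

### Filtering

Pose sequences are filtered by converting rotations to quaternions,
enforcing sign continuity (consecutive dot products ≥ 0; quaternions double
cover rotations so `q` and `-q` are the same rotation), low-pass filtering
the four quaternion and three translation components with a 2nd-order
Butterworth at 10 Hz, renormalising, and rebuilding transforms. The filter
runs forward and backward for zero phase lag — standard biomechanics
practice — with the design cutoff raised by `(√2 − 1)^(-1/4)` so the −3 dB
point of the double pass stays at 10 Hz; a causal single pass is available
by argument. Odd-reflection padding with steady-state initial conditions
makes a constant pose pass through bit-exactly; sequences must exceed the
padding length (7 frames at order 2). Renormalisation error after component
filtering is below 1e-12 at these cutoff-to-signal ratios.

Two numerical caveats are deliberate choices. First, tibial speed (central
finite differences of the tibial anatomical origin, m/s) is computed on the
transforms it is given: the synthetic trajectories are smooth, so filtering
changes speeds negligibly, and on an exactly constant-velocity segment the
unfiltered derivative recovers the set speed to 1e-9, which no zero-phase
digital filter can match at trial endpoints. Second, the *agreement*
statistics default to unfiltered per-frame poses. The emulator's noise is
independent frame to frame (by contract), and a 10 Hz zero-phase filter at
250 Hz would attenuate white noise by a factor of ~4, so filtering before
differencing would make the reported statistics describe the filter rather
than the injected tracking error. Real tracking error is temporally
correlated and largely survives such filtering; emulated white error does
not. `stratified_report(..., filter = TRUE)` restores the filtered
comparison if wanted.

## Agreement statistics

Differences are signed model − marker (Bland–Altman test-minus-reference
convention). Per DOF: MAD ± SD of |diff|; bias = mean(diff); LoA half-width
= 1.96 × sample SD (n − 1); outlier = frame with |diff − bias| exceeding
the LoA half-width by more than a 1e-9 guard (the guard makes two methods
that agree to machine precision report a zero outlier fraction and is far
below physical resolution). The LoA confidence interval uses the classical
large-sample approximation, half-width = 1.96·√(3/n)·SD; applied to
published pooled LoA values at n = 1974 it reproduces the reported bounds
(< 0.1° rotational, < 0.08 mm translational), which is the check the
acceptance suite runs. Frames are treated as independent observations, as
in the source design; autocorrelation-adjusted LoA are out of scope.

Four stratifications are produced: pooled (with CIs), per bone (from the
per-bone difference transform `marker⁻¹ ∘ model` conjugated into the
anatomical frame), per specimen, and per motion type. Stratum counts are
conserved by construction (Σ per-specimen n = Σ per-motion n = pooled n).

## Problem sizes and determinism

The bundled demo uses 33 trials (~1500–1800 trackable frames), chosen to
mirror the scale of a real session while keeping the full suite around a
minute and a half of compute. Monte-Carlo checks use 10⁴–10⁵ draws where a
distributional statement is asserted. Every random step takes an explicit
seed; identical (config, seed) pairs give bit-identical trials, CSVs and
reports, and the run manifest records all seeds plus an MD5 of the config.

## Known limitations

* The emulator's white, isotropic noise is a deliberately simple stand-in
  for 2D–3D registration error; it has no in-plane/out-of-plane anisotropy
  and no temporal correlation, both of which real systems show.
* Specimen-stratified differences arise only through sampling variation
  unless per-specimen `noise_scale` values are set; no mechanism links
  soft-tissue volume to noise.
* Trackable frames are assumed contiguous enough for uniform-sampling
  filtering; interior visibility gaps are rare with the default geometry
  but are not re-interpolated.
* Translation MADs of the default demo sit at the top of their plausible
  band (~0.7 mm) because of the two-bone lever-arm compounding described
  above; they are reported by the acceptance suite, not asserted.

## A worked miniature

```{r mini, eval = FALSE}
sps <- specimen_presets()
g <- build_geometry()
trial <- generate_trial(sps$specimen2, g, trial_config("hop", seed = 5L))
report <- stratified_report(list(trial), sps)
report[report$analysis == "pooled", ]
```

The same computation at study scale, through the file-based pipeline:

```{r pipeline, eval = FALSE}
manifest <- run_pipeline(default_config(), out_dir = "bvr_run")
utils::read.csv(file.path("bvr_run", "report.csv"))
```
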