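---
title: "Constrained whole-body kinematics from RGB-D joint centers: models, tuning and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained whole-body kinematics from RGB-D joint centers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Consumer RGB-D skeleton trackers emit per-frame estimates of ~15–25 3D
joint-center positions. Used raw, these are unusable for quantitative
rehabilitation assessment: segment lengths fluctuate by centimeters from
frame to frame and naive inverse kinematics yields physically impossible
joint angles. `bodycekf` estimates whole-body joint angles from such data
with a constrained extended Kalman filter (CEKF) built on a biomechanical
model, so that the output is *physically consistent by construction*:
segment lengths converge to constants, and every joint angle respects
physiological limits.

# The mechanical model

The chain has $N_\theta = 22$ revolute joints, $N_L = 12$ segment lengths
and maps to $N_J = 15$ tracked joint centers. Joint indices follow the
conventional numbering: $\theta_1..\theta_3$ base link,
$\theta_4..\theta_7$ right leg (hip flexion/abduction/axial rotation,
knee), $\theta_8..\theta_{11}$ left leg, $\theta_{12}$ trunk,
$\theta_{13}$/$\theta_{18}$ clavicle elevations, $\theta_{14}..\theta_{17}$
and $\theta_{19}..\theta_{22}$ the arms. Every joint rotates about its
local Z axis, stored as a unit vector in the parent frame, and the fixed
inter-frame transform is a translation that is linear in the segment
lengths. This generalizes the modified Denavit–Hartenberg screw (which
only allows an X-axis re-orientation between consecutive Z axes) just
enough to express ISB-style anatomical rotation sequences without angle
offsets; the zero pose is then exactly the reference posture (standing,
arms down, facing the camera).

Three geometric decisions deserve explanation, because the source
topology (a figure) does not fix them:

* **15 centers.** We retain spine base, spine shoulder and head centrally,
  plus shoulder/elbow/wrist and hip/knee/ankle bilaterally. Hands, feet
  and fingers are excluded as unreliable; a 5-central-point selection
  would give 17 points, which contradicts $N_J = 15$.
* **12 lengths.** A 15-node tree has 14 edges. We share the two structural
  offsets (clavicle, pelvis half-width) left/right and keep per-side limb
  lengths: trunk, head, clavicle, pelvis, 2×(upper arm, forearm, thigh,
  shank) = 12, matching $N_L$ and the 12 convergence traces such filters
  display.
* **Hip placement and rotation orders.** Hip centers sit below-lateral of
  the pelvis origin (unit direction $(\pm\sqrt{2}/2, -\sqrt{2}/2, 0)$
  scaled by the pelvis offset). With a purely lateral offset the hip
  flexion axis coincides with the base-link pitch axis and the sagittal
  DOFs (base pitch, hip flexion, trunk flexion) become exactly redundant —
  the filter then drifts freely in that null space. The vertical drop is
  anatomically correct and restores identifiability. Similarly, the
  shoulders use an abduction–flexion–axial rotation sequence: the
  axial-rotation axis aligns with the *first* axis of the sequence when
  the middle rotation reaches 90°, and the scripted tasks raise the arms
  laterally to ~85°. Abduction-first moves that gimbal lock to 90° of
  *flexion*, which none of the tasks approaches. A consequence is that
  $\theta_{14}/\theta_{19}$ are shoulder abduction and
  $\theta_{15}/\theta_{20}$ shoulder flexion in this implementation.

Default physiological limits (degrees) are in `joint_table()`; they are
deliberately literature-wide rather than task-narrow.

# The constrained filter

The state stacks $[\theta, \dot\theta, \ddot\theta, L]$ plus a 3D root
translation with constant-velocity dynamics (84 components). Measurements
are the 45 stacked joint-center coordinates; the measurement model $h$ is
the forward kinematics and $H$ its analytic Jacobian (velocity and
acceleration columns are identically zero). The transition is linear:
angles integrate velocities and accelerations, accelerations and segment
lengths are constant, and the zero process-noise rows for the lengths
force their error covariance — and hence the estimates — to converge to
constants.

The update enforces the inequality constraints $C\hat x \le d$ (two rows
per angle from the physiological limits; two per length from the ±20%
bounds around the initial estimate) through a restricted gain
$$K^R = K - C^\top (CC^\top)^{-1}(C\hat x - d)\,
  (\nu^\top S^{-1}\nu)^{-1} \nu^\top S^{-1},$$
applied with only the active (violated) rows. The violation term
$C\hat x - d$ is evaluated at the **unconstrained posterior**: simple
algebra shows the corrected estimate then lands exactly on the active
bounds, whereas evaluating it at the a-priori state (as the formula is
sometimes printed) corrects by the *prior's* violation and can push the
posterior further out whenever the prior is feasible — in our experiments
this destabilized whole trials. The literal a-priori form remains
available (`gain_violation = "prior"`). After the correction the active
set is re-checked once and any residual violation is clamped onto its
bound as a logged safety net; with the posterior reading the clamp fires
only on floating-point noise. When $\nu \approx 0$ with active
constraints the $(\nu^\top S^{-1}\nu)^{-1}$ factor is undefined and the
code falls back to clamping. The covariance uses the Joseph-stabilized
form with the gain actually applied (the plain $(I-K^R H)P^-$ form is a
switch), and is symmetrized each step; a singular innovation covariance
is jittered by $10^{-9}\,\mathrm{tr}(S)/45$ with a warning.

## Initialization

Segment lengths come from the leading 30 frames. Because white
measurement noise inflates inter-center distances
($E\|\Delta\|^2 = d^2 + 6\sigma^2$ for isotropic per-axis variance
$\sigma^2$), the estimator removes this bias using a pooled
$\hat\sigma^2 = \widehat{\mathrm{Var}}(d)/2$ obtained from the
frame-to-frame distance fluctuations; on clean data it reproduces the
true lengths exactly. Angles and root come from inverse kinematics solved
on the *average* of the leading frames: a single frame carries ~7 cm of
noise per center under the pooled noise model, and one-frame IK can land
in a mirrored arm configuration from which the filter never escapes,
while trials start at rest so the average is a valid posture.

$P_0$ is the identity on the angle, length and root blocks (the
conventional equal-influence choice), but the velocity and acceleration
blocks default to variance $10^{-4}$: trials begin in a resting posture,
and encoding that known stillness matters. With unit prior variance on
velocities, the first noisy innovations imprint spurious velocity and
acceleration on weakly observable DOFs (the axial rotations, which no
measurement can correct), and the constant-acceleration model then
integrates them quadratically until the angle pins at its limit for the
rest of the trial. The plain identity is available via
`init_from_measurements(..., p0 = "identity")`.

# Covariance tuning

**R** is assembled from Gaussian moment fits of joint-center residuals
against a reference (`fit_measurement_noise()`): per-axis moments
(x: −0.06 m, 0.0019 m²; y: +0.06 m, 0.0050 m²; z: −0.003 m, 0.0009 m²)
or the pooled lump (0, 0.0052 m²). The pooled variance exceeds the mean
per-axis variance because the axis biases differ — pooling mixes them in.

**Q, data-driven.** Per joint, an FFT of the reference trajectory gives
the amplitude $A$ (half peak-to-peak) and cutoff $\omega_{max}$ (lowest
frequency reaching 95% cumulative power, DC excluded; constant
trajectories floor at 0.1 rad/s with a warning). The published
noise-factor formula is typographically ambiguous in its exponent
grouping; the default reading is
$\sigma^2 = \big(A\,\omega_{max}^4\, e^{\omega_{max}\Delta t/4\pi}\,
\Delta t\big)^{2/(3\Delta t)}$, with
$(\cdot)^{2/3}\Delta t$ as variant `"pow23_dt"` and a user-callable
override. At 30 Hz the default reading produces astronomically large
factors that the tuning bounds $[10^{-3}, 10^2]$ clip to the upper bound
— consistent with data-driven tuning performing much worse than
optimized tuning, as reported for the original system. Per-joint factors
form blocks $\sigma^2 G G^\top$, $G = (\Delta t^3/6, \Delta t^2/2,
\Delta t)^\top$, on each joint's (angle, velocity, acceleration)
triplet.

**Q, optimized.** Eleven shared factors (4 legs, 4 arms, 1
trunk+clavicles, 1 base rotations, 1 root translation; left/right
shared) are fit by bounded least squares on the summed squared
difference between filter output and reference angles. Each objective
evaluation is a full constrained-filter run, so the landscape has broad
plateaus and quasi-Newton methods with finite-difference gradients stall
near the clipped initial point; the search therefore runs deterministic
cyclic coordinate descent over a log10 grid spanning the bounds before
an `nlminb` polish, and never returns a point worse than its start. The
initial point is the data-driven configuration clipped to the bounds.
The trust-region-reflective solver of the original work has no direct R
counterpart; box-constrained quasi-Newton plus the global sweep is the
package's equivalent. The root-translation group, which has no angle
spectrum, starts at the geometric mean of the joint factors.

# The synthetic world

`generate_task()` scripts four rehabilitation tasks — deep squat with
lateral arm raises, stepping in place, sagittal and frontal trunk tilts
— as raised-cosine repetitions (10 by default, 4 s each, 6 s for the
frontal tilt) that start and end exactly at rest, with analytic
velocities and accelerations, per-joint amplitudes chosen once to be
physiologically plausible (e.g. squat: 100° knee, 50° hip, 85° shoulder
abduction, with the pelvis drop computed from the leg geometry); the
exact experimental amplitudes were never published, so these are package
defaults exposed as parameters. Generation is deterministic — all
randomness lives in `corrupt()`, which adds white per-axis Gaussian
noise at the measured tracker moments (or the pooled isotropic model),
plus optional 0.3 m outliers and dropouts.

**Fidelity limit, and what a green test does not establish.** Real
depth-tracker error is strongly structured: a large quasi-static,
pose-dependent bias plus small frame-to-frame jitter. The printed
variances describe the *marginal* error distribution over whole
sessions; feeding that variance back as *white* noise is substantially
harsher per unit time, because none of it averages into a stable bias
the filter could ride. Degrees of freedom that are nearly unobservable
from joint centers — hip and shoulder axial rotations, and any DOF whose
distal joint is near-straight — receive per-frame angle information far
below their prior and absorb systematic drift; against synthetic ground
truth their RMSD and correlation are markedly worse than the published
values, which were computed against a multibody-optimization reference
driven by the *same* sensor data (and hence co-varying with it). Green
accuracy tests on this world therefore establish correct mechanics,
constraint handling and tuning behavior — not that the published
accuracy transfers to white noise of equal variance.

# Evaluation

RMSD and Pearson correlation are computed per angle of interest
(task-specific subsets; correlation of a constant trace is returned as
`NA`, never 0). Repetitions are time-normalized to 101 nodes (0–100% of
the movement cycle, the community convention) by linear interpolation.
The 1D SPM paired t-test compares two sets of error curves node-wise;
family-wise control is by max-|t| sign-flip permutation (default;
exhaustive when $2^n \le$ the budget) or by 1D random-field theory with
residual-based FWHM estimation and the Euler-characteristic threshold.
Cluster p-values are peak-level (the family-wise probability of reaching
the cluster's maximum |t|). Two numerical notes: zero-variance nodes cap
the t statistic at $10^6$ with a warning, and the RFT threshold is
intentionally left standard — on unsmooth (white) difference fields the
continuum approximation is conservative (empirical family-wise error
~0.01 at $\alpha = 0.05$), which is why permutation is the certified
default.

# Known limitations

* Axial rotations are structurally weakly observable from joint centers;
  limits bound, but do not remove, their error.
* The noise model is white and Gaussian; structured tracker error is only
  approximated by the outlier/dropout knobs.
* The per-frame IK reference stand-in is not the published 39-marker
  multibody optimization; tests validate against synthetic ground truth
  instead.
* No smoothing pass, adaptive R, or dynamics/force terms: the filter is
  causal and single-pass by design.
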