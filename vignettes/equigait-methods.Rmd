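---
title: "Inertial gait analysis for horses: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inertial gait analysis for horses: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigait)
```

# The problem

Equine lameness examination rests on two families of kinematic parameters.
From limb-mounted sensors on the cannon bones: the **protraction** and
**retraction** angles (forward/backward sagittal tilt of the bone relative to
vertical at the hoof-on and hoof-off moments), the **abduction** and
**adduction** angles (outward/inward coronal tilt, taken as the within-stride
extrema), and the sagittal and coronal **ranges of motion**. From sensors on
the upper body (withers, sacrum, sternum): the vertical displacement
oscillates twice per stride — once for each diagonal step — and the
differences between the two peaks (`Max_diff`), the two troughs (`Min_diff`)
and the two upward/downward amplitudes quantify left/right movement
asymmetry, summarized by the **symmetry index**

$$\mathrm{SI} = \frac{R_1 - R_2}{\max(R_1, R_2)},$$

which is 0 for perfect symmetry and ±1 when one of the two half-stride
amplitudes vanishes.

`equigait` computes all of these from 200 Hz inertial data, and — because an
inertial system must be validated against an optical motion capture (OMC)
reference that shares neither its clock nor its coordinate frame — it also
implements the cross-modality machinery that such a validation needs:
data-driven time synchronization, rigid rotational alignment, and agreement
statistics (Bland–Altman limits of agreement with repeated-measures
confidence intervals, and the intra-class correlation from a random-intercept
model). A seeded kinematic simulator stands in for the horse plus the optical
reference, so every stage is testable against exact ground truth.

# Orientation: conventions and the complementary filter

Orientations are unit quaternions, Hamilton convention, scalar first. A
quaternion $q$ maps global (navigation-frame) coordinates to sensor body
coordinates: $v_b = q \otimes (0, v_g) \otimes q^*$. The navigation frame has
its $z$-axis along gravity and an arbitrary heading: no magnetometer is used,
so there is no absolute yaw reference, and none is needed because every limb
parameter is made heading-free per stride (below).

Gyroscope integration uses the first-order form
$q_k = \mathrm{normalize}\!\left(q_{k-1} + \tfrac{1}{2}\, q_{k-1} \otimes (0,
\omega)\, \Delta t\right)$ with body rates in rad/s internally (all public
interfaces are deg/s and degrees). Differentiation of a quaternion signal is
implemented as the *exact algebraic inverse* of that step,

$$\omega_k = \frac{2\,\mathrm{vec}\!\left(q_{k-1}^* \otimes \dot q_k\right)}
{\mathrm{Re}\!\left(q_{k-1}^* \otimes q_k\right)},
\qquad \dot q_k = \frac{q_k - q_{k-1}}{\Delta t}.$$

The scalar divisor (the cosine of the half-step angle, within $10^{-4}$ of
one at gait rates) is what makes differentiate–integrate round trips
lossless; with the plain first-order formula a second-order rate error
accumulates to a few tenths of a degree over a trial at trot rotation rates.
Quaternion signals are sign-continuous by construction ($\langle q_k,
q_{k-1}\rangle \ge 0$); $q$ and $-q$ encode the same rotation and a
consistent sign is a precondition for differentiation.

Orientation estimation is a complementary filter: gyro prediction, then a
tilt-only correction that rotates the estimate toward the accelerometer's
gravity direction by a fraction `accel_gain` of the full error, about an axis
perpendicular to gravity in the body frame — so pitch and roll drift are
compensated while yaw is never touched. Free-fall samples (specific force
below half gravity) skip the correction.

Two numerical consequences of the small default gain ($10^{-4}$ at 200 Hz)
matter in practice and are encoded in the defaults:

* the correction time constant is $1/(\mathrm{gain}\cdot f_s) \approx 50$ s,
  so the **initial** orientation must already be good. A single accelerometer
  sample is polluted by motion acceleration (several m/s² during gait); the
  filter therefore initializes tilt from the mean specific force over a 2 s
  window, which cancels the periodic motion component, with yaw set to zero.
* a constant gyro bias $b$ settles at a steady-state tilt error of about
  $b\,\Delta t/\mathrm{gain}$ — 0.5 °/s of bias would equilibrate at 25°.
  The small gain therefore presumes calibrated gyroscopes; the simulator's
  default residual bias (≈0.02 °/s) reflects that operating point, and the
  test suite demonstrates the equilibrium formula explicitly rather than
  pretending the gain can absorb large biases.

# Limb angles by swing–twist decomposition

Because heading is part of the orientation, the forward-swing direction is
estimated **per stride**: the rotation between the orientations at hoof-off
and the following hoof-on, $q_r = q_{on} \otimes q_{off}^*$, is de-twisted
about the vertical axis (swing–twist decomposition $q_r = q_t \otimes q_s$
with the twist about $z$), and the residual swing rotation's axis — a
horizontal vector perpendicular to the sagittal plane — is the stride's
sagittal axis. Rotating it +90° about $z$ gives the coronal axis; for
left-side limbs the coronal axis is mirrored so that outward tilt (abduction)
is positive on either body side. The sagittal axis sign is chosen so that the
angle at hoof-on (protraction) is positive.

Per-sample angles are then the twist angles, about these axes, of the
orientation relative to the mid-stance orientation,
$q_{r,m}(t) = q_r(t) \otimes q_r^*(t_{mid})$, where mid-stance (50% of
stance, snapped to the nearest common sample) approximates the vertical
reference that neither system can observe directly. Both angles are therefore
*exactly zero at the mid-stance sample by construction*; after the optional
zero-phase smoothing of the angle signals the mid-stance value is subtracted
again so the invariant survives filtering. A welcome corollary of the
convention is that a constant heading change cancels identically in
$q_{r,m}$, which the suite verifies to $10^{-6}$ degrees.

Coronal extrema are searched over the full stride (not the swing phase only);
with stance being coronally quiet this is equivalent in practice and avoids a
second timing dependency.

# Hoof events

The timing reference for *both* systems is the IMU-side stride segmentation —
using different event sets per system would contaminate the comparison. The
shipped detector is a documented baseline, and deliberately pluggable (any
function from a recording to an event table can be substituted): stance
candidates are contiguous regions where the 15 Hz low-pass-filtered
angular-velocity magnitude stays below 20 °/s for at least 80 ms; the region
start is then refined to the nearest *preceding* acceleration-magnitude peak
(hoof impact) and the region end to the nearest *following* one (toe-off
push), each within a 0.2 s window. The refinement is what gives the detector
its accuracy: when protraction and retraction are nonzero at the events, the
quiet region necessarily begins after hoof-on and ends before hoof-off, so an
unrefined boundary would be biased by the stance ease-in/ease-out time.
Regions touching the recording edges are discarded (their transients are not
observable). On simulated walk and trot the detector locates every interior
event within 3 ms and stride durations within 2%.

# Upper-body displacement by cyclic integration

Navigation-frame vertical acceleration (gravity removed) is integrated twice,
with drift suppressed at each integration step by subtracting, within each
stride, the mean of the integrand over the previous, current and next stride
— a three-stride centred mean. The *displacement* output is deliberately not
mean-subtracted again; the remaining slow drift and floor-slope content is
removed by a fourth-order zero-phase Butterworth high-pass tuned to 2/3 of
the stride frequency, which passes the twice-per-stride signal essentially
unattenuated (the squared-magnitude response of the forward-backward pass
attenuates the once-per-stride component by ≈3–4%, the dominant term in the
package's ≈0.4 mm systematic on a 10 mm injected asymmetry). The stride
frequency itself is the reciprocal of twice the median peak-to-peak interval
of the sacrum displacement — the sacrum estimate is reused for all locations.
Derived cutoffs land at ≈0.57 Hz for walk and ≈0.87 Hz for trot with the
default gait configurations.

Within each stride exactly two maxima and two minima are selected — the two
most prominent of each kind if noise offers more candidates, in temporal
order, with `Max1` the first peak after the stride start (strides are
anchored to the reference limb's hoof-on). Upward/downward ranges follow the
peak–trough alternation with the stride treated cyclically: the second
trough's "next peak" wraps to the stride's first peak, which keeps all four
ranges defined and equal on a pure two-per-stride sinusoid. Peak prominence
is evaluated with context beyond the window edges so boundary extrema are not
penalized, and interpolated gap samples participate in the peak geometry but
can never be selected as extrema themselves.

Two robustness rules, both visible in the configuration: strides whose
windows lie within one stride period of a filter segment edge (recording
boundary or long dropout) are dropped from the symmetry tables
(`trim_strides`), because the sub-1 Hz high-pass needs about a stride to
settle; and occlusion gaps up to 0.25 s are interpolated *before* filtering
(remaining masked in all outputs) rather than splitting the signal — a split
would re-excite the high-pass transient at every gap and contaminate a stride
on each side, which on realistic ~50 ms dropouts costs far more than the
interpolation ever can.

# Cross-modality synchronization and alignment

The angular-velocity **magnitude** of one limb is computable from both
systems (raw gyroscope; numerically differentiated rigid-body quaternions)
and is invariant to the unknown relative orientation, which makes it the
natural synchronization signal. The lag maximizes the normalized correlation
coefficient over the full pairwise-valid overlap, evaluated at every integer
shift via FFT-based masked correlation sums, then refined by the vertex of a
parabola through the peak sample and its two neighbours. Clock skew is
assumed negligible. Candidate lags that retain less than half the best
achievable overlap are excluded: gait is quasi-periodic, and a sliver of
overlap correlates spuriously well at a wrong multiple of the stride period.
On 60 s band-limited signals at 20 dB SNR the 95th-percentile lag error is
≈0.4 ms. Signals are re-aligned by Kaiser-windowed-sinc fractional delay
(spherical linear interpolation for quaternion streams).

The fixed rotation between the frames comes from the Kabsch algorithm on the
per-time-instance paired 3D angular velocities: centroid subtraction,
covariance SVD, determinant correction to guarantee a proper rotation. The
translation (gyroscope bias) is reported but not applied. Windows where the
two magnitude signals disagree in variance beyond 1.0×10⁻³ (°/s)² over 10
samples are excluded first. That threshold is kept literally in the
configuration, but a caveat is documented: on signals with any broadband
noise the windowed variance differences of hundred-°/s gait signals exceed it
everywhere, so the pipeline falls back to excluding the worst-disagreeing
quartile of windows when more than 90% of samples would otherwise be lost.
Near-coplanar angular-velocity sets (rank-deficient covariance) are refused
with a diagnostic rather than silently resolved.

# Agreement statistics

Per-stride paired parameters feed a Bland–Altman analysis: bias (mean
difference), limits of agreement at ±1.96 SD of the differences, and a
regression of difference on pair mean for trend/heteroscedasticity
inspection. Because strides repeat within horses, confidence intervals for
the bias and LOAs are computed from within- and between-subject variance
components (REML random-intercept fit, Satterthwaite effective degrees of
freedom for the total variance, MOVER interval combination); with a single
subject — or one value per subject, as at trial level with one trial each —
the naive intervals are used. At `trial_mean` level the pairs are averaged
within subject-trial first; averaging independent stride noise shrinks the
LOAs, which is why trial-level agreement always looks better than per-stride
agreement and both are reported.

The ICC is $t_{00}/(t_{00} + \sigma^2/n_j)$ from a subject-grouped
random-intercept model ($t_{00}$ between-subject intercept variance,
$\sigma^2$ residual variance, $n_j$ mean group size for unbalanced data),
clipped to $[0,1]$. The response entering the model is a documented choice
(`mode`): `"raw"` stacks both systems' values — the default, reading the ICC
as reproducibility of the measurement across systems within horses — while
`"difference"` models the per-stride between-system differences. On balanced
data the REML components coincide with the one-way ANOVA closed form, which
the suite uses as an independent oracle.

# What the simulator emulates — and what it does not

The simulator is kinematic (prescribed trajectories, no force model), which
suffices because the pipeline consumes kinematics only. Per limb it
prescribes a sagittal profile with a quiet mid-stance plateau at 0°, a smooth
ease from the configured protraction after hoof-on and out to the configured
retraction before hoof-off — so the truth angles at the events equal the
configuration *exactly* — and a smooth swing arc back; the coronal angle is
an outward hump during swing. Orientations are composed as
coronal ⊗ sagittal ⊗ heading rotations (global-to-body, with the coronal sign
mirrored per body side). The upper-body vertical displacement is a
two-harmonic per-stride waveform parameterized directly by the extremum
differences the symmetry module measures, with its troughs placed near the
two diagonal mid-stances (≈13% and 63% of the stride) so every extremum lies
well inside the stride window; a peak difference `max_diff_mm` or a trough
difference `min_diff_mm` is realized exactly when injected alone, and to
within ≈0.1 mm when combined.

Gait is quasi-periodic: a smooth seeded phase modulation gives stride
durations a ≈2% coefficient of variation, shared across limbs and upper body.
This is both realistic and essential — on a perfectly periodic gait the
inter-system lag is only identifiable modulo one stride period.

Gyroscope signals are the numerical derivative of the truth orientation (so
integration recovers the truth exactly, a property the suite checks to 0.1°
over 30 s), plus residual bias and white noise. Accelerometers measure the
body-frame-rotated gravity plus motion acceleration, with 40 ms raised-cosine
hoof-impact and toe-off transients on the limb sensors (what the event
detector's refinement keys on). The OMC stream is the same analytic motion
evaluated at $t - \mathrm{lag}$ (an exact fractional delay), re-axed by the
configured relative rotation, with 1.9 mm position noise, small rigid-body
orientation noise, and random occlusion gaps.

Not emulated: soft-tissue artifact (sensors ride skin, not bone), hoof-impact
saturation and dual-range accelerometer fusion, non-straight paths, floor
slope beyond what the high-pass removes, and any force/lameness physiology.
Passing tests therefore demonstrate the correctness of the *processing*, not
the field accuracy of a physical deployment; the realistic-noise tolerances
(2° angles, ±1 mm asymmetry) were chosen at the scale such deployments
report, and the agreement tables from the built-in seven-subject synthetic
experiment reproduce the structure, not the numbers, of a hardware
validation.

# Problem sizes used in the shipped validation

The test suite and the acceptance script run at desk scale by design: trials
of 12 strides for end-to-end checks, 50-stride trials (200 limb strides) for
parameter-recovery statistics, 100 repetitions of 60 s signal pairs for the
synchronization accuracy estimate, a 7-subject × 2-gait × 2-trial experiment
(28 pipeline runs) for the agreement-table structure, and $n = 10^4$ draws
for Bland–Altman coverage. All randomness is seeded; identical configurations
reproduce bit-identical trials.

# Worked example

```{r example, eval = FALSE}
library(equigait)

trial <- simulate_trial(
  gait_config("trot", asymmetry = list(max_diff_mm = 10, min_diff_mm = 0,
                                       locations = "sacrum")),
  sensor_config(seed = 11)
)
res <- process_trial(trial)
summary(res)
res$sync                      # recovered inter-system lag
res$alignment$LF              # recovered relative rotation, residual RMSD
head(res$sym_imu$sacrum)      # per-stride symmetry parameters (IMU)
ba <- bland_altman(with(subset(res$paired,
                               group == "sacrum" & parameter == "max_diff"),
                        paired_measurements(value_imu, value_omc,
                                            subject = subject, trial = trial)))
ba
```

# Known limitations

* The complementary filter's printed gain presumes calibrated gyros and a
  good initialization; biases beyond ~0.05 °/s visibly tilt the estimate.
* Per-stride extrema are undefined for gaits without a two-per-stride
  vertical pattern (canter, gallop) and the event detector's quiet-stance
  assumption does not transfer to them; both are out of scope.
* The LOA confidence intervals use a variance-components approximation
  (Satterthwaite + MOVER); exact small-sample coverage is not claimed.
* The fixed variance-exclusion threshold is kept for fidelity but is only
  meaningful on near-noiseless signals; the adaptive fallback is what does
  the work on realistic data.
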