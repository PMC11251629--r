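---
title: "Methods: full-spectrum surface EMG simulation during voluntary movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-spectrum surface EMG simulation during voluntary movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsim)
```

## Overview

`emgsim` simulates multi-channel surface electromyography (EMG) during
voluntary hand, wrist and forearm movements as a chain of physiologically
interpretable stages. Every intermediate variable — joint angles, fibre
lengths, muscle activations, physiological parameter trajectories, motor
unit action potentials (MUAPs), spike trains — is a first-class object that
can be inspected, serialized and replaced, so the simulator can be used
both to generate synthetic datasets and to study cause–effect relationships
between the stages.

The pipeline is:

1. **Movement** — a joint-angle trajectory over a 24-DoF hand/wrist/forearm
   schema, defined by interpolating poses or read from a `.mot` motion
   file.
2. **Muscle kinematics** — normalised fibre lengths under a rigid-tendon
   assumption and muscle activations by static optimization.
3. **Parameter tracking** — conduction-velocity and motor-unit-depth
   trajectories derived from fibre length under constant muscle volume.
4. **Motor unit pools** — per-unit properties and spike trains from either
   the classical recruitment/rate-coding model or a leaky
   integrate-and-fire (LIF) cohort.
5. **MUAP model** — a deterministic line-source volume conductor that maps
   seven physiological parameters (plus a fixed per-unit latent) to a
   potential template on a 10 × 32 electrode grid, and morphs template
   sequences along the movement.
6. **EMG synthesis** — summation over units of the convolution of each
   unit's spike train with its time-varying MUAP.
7. **Analyses** — NMSE similarity with amplitude-based cropping, windowed
   RMS features, and an end-to-end data-augmentation demonstration for
   joint-angle regression.

## Movement definition and the musculoskeletal surrogate

A full musculoskeletal simulation environment is deliberately not a
dependency. The package ships a *surrogate* musculoskeletal layer: each of
the nine superficial forearm muscles (ECRB, ECRL, ED, ECU, the ulnar and
humeral heads of FCU, FDS, PL, FCR) carries constant signed moment arms,
an optimal fibre length, a tendon slack length and a maximal isometric
force. With rigid tendons the musculotendon length is affine in the joint
angles,

$$L_{mt}(t) = L_{mt,0} - \sum_d r_d\,\big(q_d(t) - q_{d,0}\big),$$

and the normalised fibre length is
$\ell(t) = (L_{mt}(t) - L_{slack})/\ell_{opt}$, clipped to a physiological
band (default $[0.5, 1.5]$). The moment-arm signs are chosen so flexor
fibres shorten during flexion and extensor fibres lengthen — the
qualitative pattern a full musculoskeletal model produces — but the
*absolute* fibre-length values are surrogate outputs and should only be
interpreted relatively.

Pose-to-pose interpolation uses a cosine (smoothstep) easing by default so
that angular velocity vanishes at each keyframe; this avoids the abrupt
fibre-length changes that piecewise-linear interpolation produces at stage
boundaries. Linear interpolation remains available via `interp = "linear"`.
Joint-range checks treat the declared ranges as closed intervals; angles
are degrees in files and the public interface and radians inside the
length/torque formulas.

Activations are estimated per sample by static optimization:
minimise $\sum_i a_i^2$ subject to
$\sum_i a_i F_{max,i}\, f_L(\ell_i)\, r_{i,d} = \tau_d$ and
$0 \le a_i \le 1$, with a Gaussian force–length factor
$f_L(\ell) = \exp\!\big(-((\ell - 1)/w)^2\big)$, $w = 0.45$ by default.
The solver maximises the smooth concave dual of this box-constrained
quadratic program with BFGS; samples whose demand exceeds capacity are
flagged and the least-squares-closest feasible activation vector is
returned. The torque helper is a single-DoF rigid-body model
$\tau = I\ddot q + b\dot q + kq$. The elastic term $kq$ is an addition to
the pure inertial–viscous helper one might expect: without it, slow
movements demand almost no torque and the estimated activations carry no
information about posture. A postural/elastic load is both physiologically
reasonable (gravity and passive tissue stiffness must be held against) and
necessary for the amplitude–angle coupling that surface EMG of wrist
muscles shows, so it is on by default (wrist: $k = 3$ N·m/rad, MCP:
$k = 0.8$ N·m/rad).

## Parameter tracking (`len2params`)

Under constant muscle volume, cross-sectional area scales as the
reciprocal of the relative fibre length
$\ell_s(t) = \ell(t)/\ell_{rest}$. Both the conduction velocity (via fibre
diameter at constant fibre volume) and the motor-unit depth (via the
radius of the cross-section) are taken to scale with the cross-section
*radius*, i.e. $\ell_s^{-1/2}$. The literature states only a positive
correlation between conduction velocity and cross-sectional area, not a
functional form; the exponents are therefore configuration parameters
(`cv_exponent`, `depth_exponent`, default $-0.5$) so an alternative law
(e.g. velocity proportional to area, exponent $-1$) is a one-line change.
The scales multiply each unit's baseline velocity/depth before being
clamped to the MUAP model's valid condition range.

## Motor unit pools

Unit sizes follow the twitch-force distribution: the classical model uses
the exponential law $\mathrm{ftw}(j) = e^{\ln(RP)\,j/N}$ (default
$RP = 100$), the LIF cohort the linear–exponential law
$\mathrm{ftw}(j) = 0.81\,(18.51\,(j/N) + 104.10\,(j/N)^{4.83})$ fitted to
human forearm data. The leading 0.81 cancels in the fibre-count
normalisation but is retained for fidelity to the published fit. Fibre
counts are allocated proportionally with largest-remainder rounding, so
they sum to the muscle total exactly and every unit keeps at least one
fibre.

Recruitment thresholds are exponentially spaced,
$\theta_j = e^{\ln(RR)\,j/N}/RR$ with recruitment range $RR = 30$, so the
last unit recruits exactly at normalised drive 1. The classical model's
constants follow the canonical parameterisation of this model family
($MFR = 8$ Hz, gain 1 Hz per excitation unit, peak rates interpolated
from 35 Hz down to 25 Hz with rank, inter-spike-interval coefficient of
variation 0.2, jitter truncated at $\pm 3.9\sigma$ to keep intervals
positive); none of these is hard-coded. The drive is normalised excitation
in $[0,1]$ and muscle activation maps to drive by identity.

The LIF cohort integrates $\dot V = (RI - V)/\tau$ per unit with forward
Euler, spike-and-reset at threshold, and an absolute refractory period.
The product $R_j I_{max,j}$ is tied to the recruitment threshold
($R I_{max} = v_{th}/\theta_j$) so recruitment order is exact by
construction; membrane time constants and refractory periods are affine in
rank between configurable endpoints chosen so that firing rates are
onion-skin ordered (earlier-recruited units fire faster at any shared
drive) — with $\tau$ and $t_{ref}$ non-decreasing in rank this ordering is
provable from the closed-form constant-input interval
$ISI = t_{ref} + \tau \ln\!\big(RI/(RI - v_{th})\big)$, which also serves
as the model's accuracy oracle (the Euler integration at 10 kHz matches it
to well under 1%).

Randomness is organised as one root seed with per-(muscle, unit, purpose)
child streams derived by hashing, so adding a unit never perturbs the
draws of the others, and every simulation is bit-reproducible.

## The MUAP model

The deep generative MUAP model that inspired this interface is *not*
reproduced here. The module implements the same seven-parameter
conditioning contract — fat-layer conductivity, fibre number, depth,
medial-lateral position, innervation-zone position, conduction velocity,
fibre length, each on a relative $(0,1]$ scale — with an analytical
line-source volume conductor, so the rest of the pipeline is exercised
against a deterministic, testable component. Externally produced MUAP
tensors in the same hierarchical layout can be read back with
`read_muap_store()`, which is the intended plug-in point for a learned
generator.

Geometry: 32 electrode columns around a cylinder (default radius 40 mm)
by 10 axial rows (10 mm apart). A fibre sits at the depth and
circumferential angle given by its condition, runs axially with its IZ at
`iz_pos` of its length. Two travelling dipole sources (spatial profile:
first derivative of a Gaussian, fixed width 4 mm) depart from the IZ in
opposite directions at the conduction velocity and extinguish as their
profile passes the fibre ends. Electrode potential is the quadrature sum
of source strength over distance, scaled by fibre number and fat
conductivity; the fat parameter additionally sets a circumferential
Gaussian smoothing width (less conductive fat blurs and attenuates). The
fixed per-unit latent perturbs the two pole amplitudes (±10%) and the IZ
(±2% of fibre length) deterministically: morphing a sequence with a fixed
latent changes templates only through the physiological parameters, and
drawing a fresh latent reproduces the prior-sampling mode.

A fixed *spatial* source width was chosen over a width tied to conduction
velocity: with a fixed profile the template is an exact time-scaling in
velocity ($\mathrm{grid}(t; 2v) = \mathrm{grid}(2t; v)$), so "doubling
velocity halves the duration" holds to within one sample, and the
qualitative response suite (depth ↓ amplitude ↑ spread, velocity ↓
duration, length ↑ duration, fibre number ∝ amplitude, IZ shifts the
onset row, medial-lateral shifts rotate the peak column) is monotone by
construction rather than approximately.

Morphing generates one template per keyframe (default 16 per movement)
with the unit's depth, velocity and length multiplied by the tracked
scales, clamped to the valid relative range; EMG synthesis linearly
interpolates the two bracketing keyframe templates at each spike time
(nearest-keyframe mode is available for speed). How a continuous template
change should be resolved per spike is not prescribed by the interface
contract; interpolation is this package's choice.

## EMG synthesis and analyses

The interference EMG is
$\mathrm{emg}[c, t] = \sum_u \sum_k M_u(t_k)[c, t - \lfloor t_k f_s
\rceil]$: each spike stamps the unit's current template at the nearest
sample (sub-sample placement is out of scope); templates truncate at the
record end. The implementation is checked against a dense FFT-convolution
oracle to $10^{-10}$ of peak. Additive white Gaussian noise is calibrated
to a requested SNR over the whole record. Output units are arbitrary —
the surrogate volume conductor is uncalibrated — so amplitude comparisons
are always within-run.

MUAP similarity uses the normalised mean square error: mean squared
difference divided by the average of the two mean-square powers, computed
on a common support. Each template is first cropped to the minimal
bounding rectangle of channels whose maximum absolute amplitude exceeds
75% of the mean of the per-channel maxima; the crop rule is iterated to
its fixpoint, which makes cropping idempotent (a single application is
not, because the threshold is recomputed on the retained channels). For a
pair, the union of the two individual crops is used — the common support
is not prescribed, and the union keeps the metric symmetric. Power is
averaged over the cropped support, consistent with cropping preceding the
similarity definition. "Maximum amplitude" is the maximum of the absolute
value, as the waveforms are biphasic.

Windowed RMS features use 200-ms windows. The phrase "50-ms overlapping"
is read literally as a 50-ms overlap, i.e. a 150-ms step; the alternative
reading (50-ms step) is available through the `step_s` argument. Windows
that would extend past the record end are dropped, giving
$\lfloor (T - 0.2)/0.15 \rfloor + 1$ windows for a $T$-second record.
Each window is labelled with the mean joint angle inside it.

## The data-augmentation demonstration

The experimental arm of the original case study (six subjects, wearable
EMG sensors, MVC normalisation) requires recordings that no simulator can
conjure; it is *emulated* here so the protocol is executable end to end.
"Real-like" trials are simulator runs under an independent perturbation
regime — stronger drive jitter, lower SNR (14 dB vs 20 dB), and a
one-column electrode misplacement — standing in for experimental
recordings. Consequently the published experimental correlation values
are **not** reproduction targets; what the package's own acceptance
checks assert is *self-consistency*: a ridge regressor trained on one
synthetic trial reaches PCC ≥ 0.8 on a second trial of the same protocol,
and the ten-shuffle label null averages within ±0.2 of zero.

Trials are 15 s, angles at 40 Hz, EMG at 2000 Hz, six channels selected
at the grid electrodes nearest FCR, FDS, FCU, ECU, ED and ECRL. The ridge
penalty defaults to 1 and can be selected by leave-one-trial-out
validation on a log grid (`select_lambda()`); the augmentation experiment
repeatedly trains on two real-like plus two synthetic trials against a
two-real-like baseline and evaluates on a held-out real-like trial,
reporting paired and unpaired comparisons (the pairing structure of such
tests is ambiguous, so both are emitted).

## Problem sizes and reproducibility

Default problem sizes were chosen as the smallest that leave every
qualitative phenomenon visible: 16 units per muscle (pools of hundreds of
units change amplitudes, not any of the tested orderings), 8–16 morph
keyframes per movement, 96–128-sample templates, 15-s trials. All
randomness flows from a single root seed through named child streams;
repeated calls with the same seed are bit-identical.

## Known limitations

* The volume conductor is an analytical surrogate: it preserves the
  seven-parameter interface and the documented monotone responses, but
  absolute amplitudes and waveform fine structure are not those of a
  trained generative model or a finite-element conductor.
* Tendons are rigid; musculotendon equilibrium with compliant tendons,
  muscle wrapping, reflex/afferent dynamics and nonlinear motoneuron
  dendritic integration are out of scope.
* Both pool models are isometric-contraction models applied during slow
  movements; rate adaptations specific to dynamic contractions are not
  modelled.
* Electrode geometry is fixed at 10 × 32 around a cylindrical forearm;
  electrode-skin impedance and motion artefacts are not modelled.
* Passing the test suite demonstrates internal consistency and the
  documented qualitative behaviour on synthetic data; it does not certify
  agreement with experimental recordings.
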