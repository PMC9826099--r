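---
title: "Models and methods in triaxmeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in triaxmeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triaxmeg)
```

# Scope

`triaxmeg` simulates and analyses magnetoencephalography (MEG) recordings
from a wearable helmet of 30 triaxial optically pumped magnetometers (OPMs,
90 channels), of the kind used to study sensorimotor beta-band dynamics
during naturalistic tasks such as handwriting. The package covers the full
computational chain: helmet geometry and rigid-body motion; forward modelling
of neural and environmental fields; the OPM gain-error model; background-field
mapping and coil nulling; dynamic drift stabilization; a synthetic paradigm
generator with planted ground truth; LCMV beamformer imaging in triaxial or
radial-only mode; amplitude-envelope-correlation (AEC) connectomics; and
repeatability ("fingerprinting") statistics. Everything runs on synthetic
data whose generating parameters are known exactly, so each analysis stage
can be validated against planted truth or closed-form identities.

# Coordinate conventions and units

Head coordinates are right-handed with the origin at the center of the
best-fitting head sphere, x anterior, y left, z superior; positions are in
meters. Channel data are in tesla internally; background fields are reported
in nT and nT/m, and sensor noise in fT/sqrt(Hz). Channels are ordered
sensor-major with axis tags x, y, z per sensor; the z axis of each triad is
the outward radial direction, and `radial_channel_mask()` re-derives the
radial tag as the axis with the largest absolute projection on the sensor's
radial direction (ties break in axis order).

# Forward models

**Neural sources.** A current dipole inside a homogeneous conducting sphere
has a closed-form external field (the Sarvas solution), including the
volume-current term. We use it instead of a realistic single-shell boundary
model because it is provably correct against analytic identities: a purely
radial moment is externally silent, the field is linear in the moment, and
the radial field component equals the radial component of the free-space
Biot-Savart field of the primary current. These identities are asserted in
the test suite. The consequence is that source-space results are validated
against the package's own ground truth, not against anatomy.

Leadfields are channels x 2 matrices for unit dipoles along the two
source-tangential directions; radial source components are omitted because
the spherical conductor renders them invisible. A source on the sphere
center is handled with a deterministic fallback tangential basis and a
message.

**Background field.** The remnant quasi-static field inside the shielded
room is modelled as three uniform components plus a symmetric trace-free
gradient tensor parameterized by five independent components
(Gxx, Gyy, Gxy, Gxz, Gyz, with Gzz = -Gxx - Gyy). This choice of basis is a
documented convention; any five independent components of a trace-free
symmetric tensor would span the same model space.

**Interference.** A sinusoidal line source (default 16.6 Hz, the frequency
of a typical air-conditioning artifact) with the spatial pattern of a
distant magnetic dipole (default 5 m away), normalized so its strongest
channel sees a configurable amplitude (default 1 pT). At 5 m the pattern is
nearly uniform across the helmet (< 15% spread), which is exactly the regime
in which triaxial beamforming can separate it from cranial sources.

**Coil system.** Eight compensation coils produce the eight field
coefficients through an invertible calibration matrix; the default adds 5%
seeded off-diagonal leakage so that current computation genuinely exercises
the matrix inversion.

# OPM gain error

In the spin-exchange relaxation-free regime an OPM's responsivity falls as
the quasi-static field at the cell departs from zero. We model the gain
error as a Lorentzian zero-field resonance,

  eps(dB) = x / (1 + x),  x = (dB / Gamma)^2,

with half-width Gamma calibrated from a single anchor: a 3 nT step producing
a 3.8% gain error gives Gamma = 15.09 nT. The validation of this one-knob
model is that it then reproduces two further published working points
without refitting: a 90 degree rotation in a 0.2 nT nulled field gives a
0.018% error, and a task-scale ~10 degree rotation gives ~0.0005%. The field
step under a rotation by theta in a uniform field of magnitude B is modelled
as dB = B sin(theta) (a sensor zeroed at rest, rotated in a uniform field);
translation-through-gradient contributions are excluded from this particular
bookkeeping, which is the assumption that reproduces the printed working
points. A note on internal consistency: a 5% error at 3 nT (the nominal
dynamic-range quote) would imply Gamma = 13.08 nT rather than 15.09 nT; the
package calibrates from the 3.8% anchor and exposes
`calibrate_linewidth()` so either convention can be chosen.

Sensor noise is white with a configurable amplitude spectral density
(default 15 fT/sqrt(Hz)); the per-sample standard deviation is
density * sqrt(fs / 2). No 1/f knee is modelled.

# Background-field mapping and nulling

OPMs are field-zeroed by on-sensor coils before acquisition, so the absolute
field is unobservable; only motion-induced signal changes identify the
background model. The mapping fit therefore includes a per-channel DC offset
as a nuisance parameter, projected out by within-channel centering
(Frisch-Waugh), and regresses the moved-frame projections
a_i(t)' (b0 + G p_i(t)) on the eight coefficients. The fit uses the triaxial
channels of five sensors spread over the helmet (front, back, top, left,
right), a 60 s mapping movement at 120 Hz with two-tone sinusoidal
excitation of all six degrees of freedom (default amplitudes 10 degrees and
5 cm — the scale of natural task movements), and reports the design
condition number. Rank deficiency (e.g., no motion) raises an error naming
the unidentifiable components.

Nulling iterates mapping -> fit -> opposing DC currents
(I = -calibration^{-1} coefficients), twice by default, followed by a final
mapping pass that measures the residual. For a model-compliant noiseless
background one iteration is exact to numerical precision; with 15
fT/sqrt(Hz) noise the 16-session median residual is far below the 0.2 nT
and 2.0 nT/m levels achieved on real hardware, because the simulation
contains none of the tracking, reference-motion or calibration errors that
dominate in practice. The package reports residuals as Euclidean norms of
the three uniform components and of the five gradient coefficients.

**Dynamic stabilization** runs a discrete 60 Hz proportional-integral loop
on eight reference channels (four dual-axis sensors behind the helmet,
separated ~40 cm in z but sharing x and y, so only the three uniform
components and the three z-varying gradients are identifiable — gradients
varying in x and y are uncontrollable with this geometry). References are
low-pass filtered at 3 Hz (single-pole); the six compensable components are
estimated by least squares and a velocity-form PI update drives the coils.
Default gains (kp = 0.5, ki = 6*pi per second) give integral elimination of
constant offsets, >= 10x attenuation of 0.1 Hz drift, and near-transparency
(< 1.2x) above the cutoff; divergence raises an error carrying the last
stable iterate.

# The synthetic paradigm

The generator emulates a handwriting experiment: two blocks of 20 trials
(5 s stimulus + 7 s rest, 1200 Hz), one block per hand, with stimulus and
block triggers embedded. Each of 78 regions (a seeded random proxy for a
cortical parcellation, with the first two regions fixed near the left and
right sensorimotor cortices) carries a beta-band (13-30 Hz) Gaussian
carrier modulated by:

* a trial-locked profile: baseline 1, suppression to (1 - ERD depth) during
  writing, elevation to (1 + rebound gain) in the post-movement rebound
  window, with 0.4 s raised-cosine transitions. Rebound timing is
  condition-dependent — 5.5-7.5 s for right-handed writing, 9-11 s for
  left-handed (writing with the non-dominant hand takes longer). Right-handed
  writing plants a strongly lateralized suppression (left motor region deep,
  right shallow); left-handed writing plants a bilateral response.
* a slow log-normal envelope (smoothed Gaussian processes, sigma = 0.35)
  whose cross-region correlation is set from the planted connectome. Because
  the stochastic carrier attenuates envelope correlation downstream, the
  modulator correlation is divided by a calibration slope measured once per
  session by simulation (`coupling_calibration()`, internal fixed seed) so
  that the *measured* AEC matches the planted value. Planted coupling for
  left-handed writing is globally elevated with a stronger right-sensorimotor
  node and a 0.40 interhemispheric sensorimotor edge (0.15 for right-handed
  writing), matching the direction of the condition effects the analysis is
  meant to detect.

Head and helmet move as one rigid body, so the head-to-sensor geometry — and
with it the leadfield of the isotropic spherical conductor — is invariant
under task motion. Motion therefore enters the data through (a) the
quasi-static background-field artifact a_i(t)' B_bg(p_i(t)) - a_i(0)'
B_bg(p_i(0)) per channel, computed at the 120 Hz motion rate and
interpolated to the channel rate, and (b) the per-channel gain error implied
by the channel's largest quasi-static field step. Word stimuli, eye/muscle
artifacts, cross-axis projection errors, sensor crosstalk and 16-bit
quantization are not modelled; the sensor noise floor dominates the
quantization step, and the other omissions mean that passing tests
demonstrate correctness of the analysis chain, not robustness to every
real-world artifact.

Source amplitudes default to 5 nA.m for the sensorimotor regions (other
regions 40% of that), chosen once so that the best channel's envelope SNR
and the triaxial/radial summed-SNR ratio land in the range reported for
real 20-trial recordings; they are configuration, not claims.

# Reconstruction

Preprocessing removes per-channel means, applies an optional channel
exclusion list, and epochs on stimulus triggers grouped by block condition.
Filtering is zero-phase (forward-backward) Butterworth of order 4 per pass
— effective order 8 — chosen to avoid phase-distorting the envelopes; the
beta band is 13-30 Hz. Data covariance is estimated per condition from
concatenated filtered trials and Tikhonov-regularized as
C + mu * lambda_max * I with mu = 0.05.

LCMV weights are unit-gain: w = C^-1 L eta / (eta' L' C^-1 L eta). The
source orientation eta within the tangential plane maximizes output SNR: it
is the minimum-eigenvalue generalized eigenvector of
(L' C^-2 L) eta = lambda (L' C^-1 L) eta (Sekihara's optimal orientation),
solved in closed form for the 2x2 problem inside voxel loops. Radial-only
mode restricts every step — covariance, leadfield rows, weights — to the
radial-tagged channels, so the two modes agree exactly when the tangential
channels are excluded by hand.

Pseudo-T images use the symmetric normalized power contrast
T = (P_active - P_control) / (P_active + P_control), with P the
beamformer-projected band power per second in the window. The exact
normalization used in the original pseudo-T literature is not printed in
one canonical form; the symmetric difference is adopted because it is
bounded in [-1, 1] and unit-free. Windows are half-open [start, end) in
seconds from stimulus onset, with two named presets: "imaging" (active
1.5-3.5 s against the condition's rebound window) and "modulation" (active
2-4 s / control 5-7 s for right-handed writing; 4-6 s / 8-10 s for
left-handed). Peaks are arg-extrema of |T| with lowest-linear-index
tie-breaking; repeatability is the mean Euclidean distance of per-run peaks
to their cross-run average. Virtual electrodes and the per-region time
courses apply condition-specific weights to the band-filtered data; the
time-frequency spectrum uses either broadband or band-limited covariance
(both exposed; broadband is the default for TFS).

# Connectomics and statistics

AEC connectomes use pairwise orthogonalization: for each region pair, one
time course is regressed out of the other; both Hilbert envelopes are
block-averaged to 10 Hz (anti-alias mean binning rather than decimation —
the envelopes are smooth, so aliasing is negligible) and
Pearson-correlated; the two regression directions are averaged to keep the
matrix symmetric (the standard resolution of the direction asymmetry). An
exactly collinear pair leaves a residual that is pure floating-point
round-off — a scalar multiple of the regressor — so residuals with
negligible variance relative to the original signal are treated as fully
explained leakage (correlation 0). Zero-variance regions get NA edges and a
warning.

Whole-brain connectivity sums the n(n-1)/2 = 3003 unique pairs of a
78-region matrix; node strength sums a region's 77 edges. Beta modulation
is mean(control envelope) - mean(active envelope), positive for the
canonical suppression-plus-rebound response. Channel SNR is the absolute
active-control envelope difference over the active-window envelope standard
deviation. The interference ratio is the excess Welch PSD at the line
frequency over the mean PSD at its neighbours (15.5 and 17.7 Hz), using
10 s Hann segments with 50% overlap and nearest-bin lookup; records shorter
than 10/1.1 s are rejected.

Rank-sum contrasts use the exact enumeration for groups of up to 10 without
ties (the normal approximation otherwise), with Bonferroni correction
capped at 1; completely tied groups return p = 1. The fingerprint test
correlates 16 run-level feature vectors (8 runs x 2 participants; connectome
inputs use only the upper triangle), splits the 120 correlations into 56
within-participant (28 unordered run pairs per participant) and 64
between-participant (all 8 x 8 ordered run combinations — the counting that
matches the published totals), and permutes the 120 values 100,000 times by
default. The one-sided p (within > between) includes the +1 correction so
p > 0 always; under a pure-noise null the p-values are uniform, which the
test suite checks with a Kolmogorov-Smirnov test at reduced permutation
count.

# Problem sizes and numerical choices

The test suite runs every stage at reduced problem sizes chosen to keep the
full suite in the tens of minutes on one CPU while preserving each
quantity's operating regime: mapping fits use the full 60 s x 120 Hz design
(the fit cost is trivial); imaging tests use 4 mm grids over a sensorimotor
region of interest and 1 mm grids over a 16 mm cube; channel-SNR runs keep
the full 20 trials per block (the SNR regime depends on trial count) but a
240 Hz rate and a reduced parcellation; permutation-uniformity checks use
2,000 permutations over 200 repetitions. Sampling at 240-300 Hz preserves
every analysis band (beta, the 16.6 Hz line and its neighbours) with ample
Nyquist margin. All randomness flows through named integer seeds; derived
seeds stay below 2^31.

Degenerate inputs are handled deterministically: coplanar points fail the
sphere fit with a named error; sources at the sphere center get a fallback
tangential basis; voxels with ill-conditioned 2x2 output matrices image as
0; singular coil calibrations and empty analysis windows raise errors.

# Known limitations

The spherical conductor and spherical-shell "parcellation" are stand-ins
for anatomy: localization accuracy here measures the analysis chain, not
coregistration or head-model error. The nulling simulation omits tracking
noise and coil miscalibration, so its residuals are optimistic relative to
hardware. The gain model is scalar per channel (no cross-axis projection
errors). The synthetic envelope coupling is stationary within a block;
nonstationary connectivity is out of scope. Recording containers use RDS
serialization with a JSON sidecar; no vendor MEG formats are read or
written.
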