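# triaxmeg

Simulation and analysis of **triaxial OPM-MEG**: magnetoencephalography
recorded with a wearable helmet of optically pumped magnetometers (OPMs)
that measure all three components of the magnetic field at each site
(30 sensors, 90 channels). The package is aimed at MEG methodologists who
want a fully synthetic, ground-truth-bearing testbed for the computational
chain of such a system:

* **Background-field mapping and nulling.** SERF-regime OPMs are only linear
  near zero field; the remnant field B(r) = b0 + G r (three uniform
  components, five independent gradient components of the symmetric
  trace-free tensor G) is identified by regressing motion-resolved channel
  data on the moved sensor geometry, y_i(t) = a_i(t)ᵀ(b0 + G p_i(t)) + c_i,
  and cancelled with biplanar coil currents I = −C⁻¹β̂. A 60 Hz PI loop on a
  reference array stabilizes slow drift.
* **OPM gain error.** A Lorentzian zero-field resonance,
  ε(ΔB) = x/(1+x), x = (ΔB/Γ)², calibrated from a single anchor
  (3.8% at a 3 nT step ⇒ Γ ≈ 15.1 nT), with the rotation step
  ΔB = B sin θ.
* **Forward modelling.** Current dipoles in a homogeneous conducting sphere
  (Sarvas closed form, volume currents included), a distant-dipole
  16.6 Hz interference line, and white sensor noise (fT/√Hz).
* **Synthetic paradigm.** Two blocks × 20 trials of "handwriting" with
  planted beta-band (13–30 Hz) event-related desynchronization, a
  condition-dependent post-movement rebound (5.5–7.5 s right-handed,
  9–11 s left-handed), lateralization, and a planted envelope-coupling
  connectome realized by shared log-normal drives.
* **Reconstruction.** Unit-gain LCMV beamforming,
  w = C⁻¹Lη / (ηᵀLᵀC⁻¹Lη), with Sekihara's optimal tangential orientation
  (minimum-λ generalized eigenvector of (LᵀC⁻²L)η = λ(LᵀC⁻¹L)η),
  pseudo-T imaging T = (Pₐ − P꜀)/(Pₐ + P꜀) on 4 mm or 1 mm grids, in
  triaxial or radial-only mode.
* **Connectomics and statistics.** Pairwise-orthogonalized amplitude
  envelope correlation (78 × 78), whole-brain (3003-pair) and node-strength
  (77-edge) summaries, exact Wilcoxon rank-sum contrasts with Bonferroni
  correction, and a 100,000-permutation fingerprinting test of 56
  within- versus 64 between-participant correlations.

## Worked example

```r
library(triaxmeg)

## gain error of a nulled-field head rotation
gm <- calibrate_linewidth(anchor_step_nT = 3, anchor_error = 0.038)
gain_error(rotation_field_step(0.2, 90), gm) * 100   # percent

## null a 3 nT / 3.4 nT/m background with two mapping iterations
array <- build_helmet_array(30)
g <- c(1, -0.5, 0.3, 0.2, -0.1)
env <- background_field(c(1, 1, 1) / sqrt(3) * 3.0, g / sqrt(sum(g^2)) * 3.4)
nul <- run_nulling(env, default_coil_system(seed = 2), array,
                   nm = noise_model(15, 3), iterations = 2, seed = 1)
nul

## simulate a handwriting session in the nulled field and localize the
## planted sensorimotor source
p   <- generate_participant(1, seed = 8, n_regions = 12)
rec <- generate_recording(p, paradigm(trials_per_block = 10, fs = 240),
                          array = array, env = nul$true_residual,
                          motion = "task", nm = noise_model(15), seed = 9)
seg   <- preprocess(rec)
truth <- planted_truth(p, "right")
grid  <- voxel_grid(head_model(), spacing = 0.004,
                    bbox = rbind(truth$peak_position - 0.014,
                                 truth$peak_position + 0.014))
pseudo_t_image(seg, "right", grid = grid, head = head_model())
```

which prints

```
[1] 0.01755294
Static-field nulling report
  pre : |B0| = 3 nT, |G| = 3.4 nT/m
  post: |B0| = 1.76e-05 nT, |G| = 6.75e-05 nT/m  (2 iterations)
source_image (triaxial): 459 voxels at 4 mm spacing
  extremum T = -0.773 at (-19.0, 39.3, 56.3) mm
```

Reading the numbers: after nulling, a 90° head rotation changes sensor gain
by only 0.018% (versus 3.8% in the un-nulled 3 nT field); the two mapping
iterations drive the simulated remnant field from 3 nT to the fit-noise
floor; and the pseudo-T extremum is negative (beta suppression during
writing) at (−19, 39, 56) mm — within one 4 mm voxel of the planted left
sensorimotor dipole at (−17.0, 37.3, 54.3) mm.

The pseudo-T window presets, beta-modulation metric, channel SNR, the
16.6 Hz interference ratio, AEC connectomes and the fingerprinting
permutation test are exposed as `window_preset()`, `beta_modulation()`,
`channel_snr()`, `interference_ratio()`, `aec_connectome()` and
`fingerprint_test()`; `run_pipeline()` sequences the whole chain from a
`run_config()`, and `inst/scripts/triaxmeg.R` wraps it for shell use.

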