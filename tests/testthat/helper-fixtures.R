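# Shared small fixtures (built in code; nothing is read from disk).

fix_head <- head_model()
fix_array <- build_helmet_array(30)
fix_radial_mask <- radial_channel_mask(fix_array, fix_head)

# random proper rotation (seeded by caller)
random_rotation <- function() {
  euler_rotation(stats::runif(1, -pi, pi), stats::runif(1, -pi / 2, pi / 2),
                 stats::runif(1, -pi, pi))
}

# exact points on a sphere, optionally jittered
sphere_points <- function(n, center, radius, jitter = 0) {
  u <- matrix(stats::rnorm(3 * n), n)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * radius
  if (jitter > 0) pts <- pts + matrix(stats::rnorm(3 * n, sd = jitter), n)
  sweep(pts, 2, center, `+`)
}

# small source-level simulation of coupled beta-band region time courses
coupled_region_sim <- function(target, duration, fs, seed) {
  local_rng(seed, {
    nt <- round(duration * fs)
    W <- triaxmeg:::.coupling_to_modulator(target, coupling_calibration())
    E <- triaxmeg:::.coupled_envelopes(W, nt, fs)
    carriers <- t(vapply(seq_len(nrow(target)),
                         function(i) bandpass(stats::rnorm(nt), 13, 30, fs),
                         numeric(nt)))
    E * carriers
  })
}
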