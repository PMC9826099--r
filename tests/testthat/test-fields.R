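test_that("conducting-sphere dipole field obeys closed-form identities", {
  hm <- fix_head
  d <- dipole(c(0.02, 0.03, 0.04), c(1e-9, -2e-9, 0.5e-9))
  at <- rbind(c(0, 0.05, 0.11), c(0.08, -0.04, 0.06), c(-0.05, 0.02, 0.09))
  B <- dipole_field(d, at, hm)
  # radial component equals the Biot-Savart (free-space) radial component
  Bfs <- dipole_field_freespace(d, at)
  for (i in 1:3) {
    rhat <- at[i, ] / sqrt(sum(at[i, ]^2))
    expect_equal(sum(B[i, ] * rhat), sum(Bfs[i, ] * rhat), tolerance = 1e-12)
  }
  # purely radial moment is externally silent
  dr <- dipole(c(0.02, 0.03, 0.04), c(0.02, 0.03, 0.04) * 1e-7)
  expect_lt(max(abs(dipole_field(dr, at, hm))), 1e-18)
  # linearity in the moment
  d2 <- dipole(d$position, 2 * d$moment)
  expect_equal(dipole_field(d2, at, hm), 2 * B, tolerance = 1e-14)
  # domain errors
  expect_error(dipole_field(d, c(0, 0, 0.05), hm), "outside")
  expect_error(dipole_field(dipole(c(0, 0, 0.1), c(1, 0, 0)), at, hm),
               "inside")
})

test_that("leadfields have the right shape, radial projection and equivariance", {
  hm <- fix_head
  src <- c(-0.02, 0.03, 0.05)
  L <- leadfield(fix_array, src, hm)
  expect_equal(dim(L), c(90L, 2L))
  # radial channels reproduce the free-space radial projection
  basis <- attr(L, "basis")
  rmask <- fix_radial_mask
  for (j in 1:2) {
    Bfs <- dipole_field_freespace(dipole(src, basis[, j]),
                                  fix_array$positions)
    rhat <- fix_array$positions / sqrt(rowSums(fix_array$positions^2))
    expect_equal(L[rmask, j], rowSums(Bfs * rhat), tolerance = 1e-10)
  }
  # co-rotating array and source leaves the leadfield invariant
  set.seed(3)
  R <- random_rotation()
  arr_rot <- apply_motion(fix_array, rigid_transform(R, c(0, 0, 0)))
  L_rot <- leadfield(arr_rot, as.numeric(R %*% src), hm)
  # the tangential source basis also rotates; compare the basis-independent
  # projector L L'
  P1 <- L %*% t(L); P2 <- L_rot %*% t(L_rot)
  expect_equal(P1, P2, tolerance = 1e-8)
})

test_that("leadfield magnitude decreases monotonically with source depth", {
  hm <- fix_head
  dir <- c(-0.25, 0.55, 0.8)
  dir <- dir / sqrt(sum(dir^2))
  radii <- seq(0.075, 0.03, length.out = 10)
  norms <- vapply(radii, function(r)
    norm(leadfield(fix_array, dir * r, hm), "F"), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("background field evaluates the harmonic uniform+gradient model", {
  bg <- background_field(c(1, 2, 3), c(1, 0, 0, 0, 0))
  expect_equal(as.numeric(background_at(bg, c(0, 0, 0))), c(1, 2, 3))
  G <- gradient_tensor(bg)
  expect_equal(G[3, 3], -1)                       # trace-free constraint
  expect_equal(G, t(G))
  expect_equal(sum(diag(G)), 0, tolerance = 1e-12)
  # divergence and curl vanish on a finite-difference stencil
  bg2 <- background_field(c(0.5, -1, 2), c(1, -0.5, 0.3, 0.2, -0.1))
  h <- 1e-3
  p0 <- c(0.02, -0.01, 0.03)
  J <- matrix(0, 3, 3)   # J[i, j] = dB_i/dx_j
  for (j in 1:3) {
    dp <- numeric(3); dp[j] <- h
    J[, j] <- (background_at(bg2, p0 + dp) - background_at(bg2, p0 - dp)) /
      (2 * h)
  }
  expect_lt(abs(sum(diag(J))), 1e-10)
  expect_lt(max(abs(J - t(J))), 1e-10)
})

test_that("coil system produces invertible calibration and config round-trips", {
  coils <- default_coil_system(seed = 4)
  expect_true(is.finite(coils$condition_number))
  out <- coil_output(coils, rep(1, 8))
  expect_equal(c(out$b0, out$g), as.numeric(coils$calibration %*% rep(1, 8)))
  # JSON round trip
  bg <- background_field(c(1, 2, 3), c(1, -0.5, 0.3, 0.2, -0.1))
  expect_equal(field_config_from_json(field_config_json(bg)), bg)
  coils2 <- field_config_from_json(field_config_json(coils))
  expect_equal(coils2$calibration, coils$calibration, tolerance = 1e-15)
})

test_that("interference source has a near-uniform far-field pattern and a 16.6 Hz line", {
  src <- interference_source(frequency = 16.6, amplitude = 1e-12,
                             position = c(5, 0, 0))
  pat <- triaxmeg:::interference_pattern(src, fix_array)
  expect_equal(max(abs(pat)), 1e-12)
  # field-vector magnitude varies little across the helmet for a 5 m source:
  # use an array with identity triads so channels x,y,z give the full vector
  axes_id <- array(diag(3), dim = c(3, 3, 30))
  arr_id <- sensor_array(fix_array$positions, axes_id)
  pat_id <- triaxmeg:::interference_pattern(src, arr_id)
  mags <- sqrt(colSums(matrix(pat_id, 3)^2))
  expect_lt((max(mags) - min(mags)) / max(mags), 0.15)
  # zero amplitude gives zero channels
  src0 <- interference_source(amplitude = 0)
  expect_true(all(interference_at(src0, fix_array, seq(0, 1, 0.01)) == 0))
  # dominant spectral line at 16.6 Hz over 10 s
  fs <- 300; tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- interference_at(src, fix_array, tt)[which.max(abs(pat)), ]
  ps <- welch_psd(x, fs)
  expect_equal(ps$freq[which.max(ps$psd)], 16.6, tolerance = 0.15)
})

test_that("field contributions superpose and vanish when all are off", {
  p <- generate_participant(1, seed = 2, n_regions = 4)
  prd <- paradigm(trials_per_block = 1, fs = 200)
  rec0 <- generate_recording(p, prd, array = fix_array, env = NULL,
                             interference = NULL, nm = NULL, seed = 3)
  # with sources present channels are nonzero; kill amplitudes for silence
  p0 <- p
  for (r in seq_along(p0$sources)) p0$sources[[r]]$amplitude <- 0
  p0$amplitudes[] <- 0
  rec_silent <- generate_recording(p0, prd, array = fix_array, env = NULL,
                                   interference = NULL, nm = NULL, seed = 3)
  expect_true(all(rec_silent$data == 0))
  expect_gt(max(abs(rec0$data)), 0)
})
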