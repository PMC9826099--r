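make_seg <- function(seed = 21, n_regions = 6, ntr = 4, fs = 200,
                     nm = noise_model(15), ...) {
  p <- generate_participant(1, seed = seed, n_regions = n_regions)
  prd <- paradigm(trials_per_block = ntr, fs = fs)
  rec <- generate_recording(p, prd, array = fix_array, nm = nm,
                            seed = seed + 100, ...)
  list(p = p, rec = rec, seg = preprocess(rec))
}

test_that("preprocessing segments trials, zeroes means and excludes channels", {
  s <- make_seg()
  expect_equal(dim(s$seg$trials$left)[3], 4L)
  expect_equal(dim(s$seg$trials$right)[3], 4L)
  expect_equal(dim(s$seg$trials$left)[2], 12 * 200)
  # per-channel means of the continuous data are removed
  centered <- s$rec$data - rowMeans(s$rec$data)
  expect_lt(max(abs(rowMeans(centered))) / max(abs(centered)), 1e-14)
  # excluding one triaxial sensor retains 87 of 90 channels
  seg87 <- preprocess(s$rec, exclude_channels = c(4, 5, 6))
  expect_equal(dim(seg87$trials$left)[1], 87L)
  # missing triggers
  broken <- s$rec; broken$triggers <- broken$triggers[0, ]
  expect_error(preprocess(broken), "trigger")
})

test_that("zero-phase Butterworth bandpass has unit passband and kills DC", {
  fs <- 600
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  mid <- seq(2 * fs, 8 * fs)   # discard transients
  y20 <- bandpass(sin(2 * pi * 20 * tt), 13, 30, fs)
  amp20 <- max(abs(y20[mid]))
  expect_gte(amp20, 0.95); expect_lte(amp20, 1.0)
  y5 <- bandpass(sin(2 * pi * 5 * tt), 13, 30, fs)
  expect_lt(max(abs(y5[mid])), 0.01)
  ycst <- bandpass(rep(2, length(tt)), 13, 30, fs)
  expect_lt(max(abs(ycst[mid])), 1e-8)
  expect_error(bandpass(tt, 13, 400, fs), "Nyquist")
})

test_that("regularized covariance shifts the spectrum as specified", {
  set.seed(2)
  X <- matrix(stats::rnorm(40 * 400), 40)
  cv <- estimate_covariance(X, mu = 0.05)
  evr <- eigen(cv$C_reg, symmetric = TRUE, only.values = TRUE)$values
  ev <- eigen(cv$C, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(max(evr), (1 + 0.05) * max(ev), tolerance = 1e-12)
  expect_gte(min(evr), 0.05 * max(ev))
  expect_identical(estimate_covariance(X, mu = 0.05)$C, cv$C)
  # rank deficiency is flagged
  Xdef <- rbind(X[1, ], X[1, ], X[2, ])
  expect_warning(estimate_covariance(Xdef, mu = 0), "rank deficient")
  expect_error(estimate_covariance(X[, 1:50]), "2x channels")
})

test_that("LCMV weights match a constrained-quadratic-program oracle", {
  set.seed(3)
  # 4-channel toy problem
  A <- matrix(stats::rnorm(16), 4); C <- crossprod(A) + diag(4)
  L <- matrix(stats::rnorm(8), 4)
  sol <- lcmv(C, L)
  expect_true(sol$unit_gain)
  g <- as.numeric(L %*% sol$orientation)
  expect_equal(sum(sol$weights * g), 1, tolerance = 1e-10)
  # oracle: minimize w'Cw subject to w'g = 1 via the KKT linear system
  K <- rbind(cbind(2 * C, g), c(g, 0))
  w_oracle <- unname(solve(K, c(numeric(4), 1))[1:4])
  expect_equal(sol$weights, w_oracle, tolerance = 1e-8)
  # the optimal orientation maximizes output SNR (power over white-noise
  # gain): (w'Cw)/(w'w) = (g'C^-1 g)/(g'C^-2 g); it beats 50 random ones
  snr_of <- function(eta) {
    g <- as.numeric(L %*% eta)
    as.numeric(t(g) %*% solve(C, g)) /
      as.numeric(crossprod(solve(C, g)))
  }
  vals <- replicate(50, { e <- stats::rnorm(2); snr_of(e / sqrt(sum(e^2))) })
  expect_gte(snr_of(sol$orientation) * (1 + 1e-9), max(vals))
})

test_that("virtual electrodes recover matched sources and reject distant ones", {
  set.seed(4)
  hm <- fix_head
  src <- c(-0.02, 0.035, 0.05)
  L <- leadfield(fix_array, src, hm)
  eta <- c(0.8, 0.6)
  q <- bandpass(stats::rnorm(4000), 13, 30, 200)
  X <- (L %*% eta) %*% t(q) + matrix(stats::rnorm(90 * 4000, sd = 1e-16), 90)
  C <- estimate_covariance(X, mu = 0.05)
  sol <- lcmv(C, L)
  # unit gain: matched location recovers q up to sign
  s_hat <- virtual_electrode(sol, (L %*% eta) %*% t(q))
  expect_gt(abs(stats::cor(s_hat, q)), 1 - 1e-10)
  expect_equal(max(abs(abs(s_hat) - abs(q))) / max(abs(q)), 0, tolerance = 1e-6)
  expect_true(all(virtual_electrode(sol, matrix(0, 90, 10)) == 0))
  # distant location: suppressed output
  far <- c(0.03, -0.035, 0.04)
  sol_far <- lcmv(C, leadfield(fix_array, far, hm))
  v_far <- stats::var(virtual_electrode(sol_far, X))
  v_near <- stats::var(virtual_electrode(sol, X))
  expect_lt(v_far / v_near, 0.1)
})

test_that("pseudo-T images are bounded, null under equal power, peak at source", {
  s <- make_seg(seed = 31, n_regions = 4, ntr = 4, fs = 200)
  truth <- planted_truth(s$p, "right")
  grid <- voxel_grid(fix_head, spacing = 0.004,
                     bbox = rbind(truth$peak_position - 0.014,
                                  truth$peak_position + 0.014))
  img <- pseudo_t_image(s$seg, "right", grid = grid, head = fix_head)
  expect_true(all(img$values >= -1 & img$values <= 1))
  pk <- image_peak(img)
  expect_lt(sqrt(sum((pk$position - truth$peak_position)^2)), 0.0045)
  expect_lt(pk$value, 0)   # power decrease in the active window
  # equal windows give a null image
  img0 <- pseudo_t_image(s$seg, "right",
                         windows = list(active = c(1, 3), control = c(1, 3)),
                         grid = grid[1:5, , drop = FALSE], head = fix_head)
  expect_equal(img0$values, rep(0, 5), tolerance = 1e-12)
  expect_error(pseudo_t_image(s$seg, "right",
                              windows = list(active = c(3, 3),
                                             control = c(5, 7)),
                              grid = grid, head = fix_head), "empty")
})

test_that("radial mode equals triaxial mode on the radial channel subset", {
  s <- make_seg(seed = 41, n_regions = 4, ntr = 3, fs = 200)
  grid <- voxel_grid(fix_head, spacing = 0.008,
                     bbox = rbind(c(-0.03, 0.01, 0.03), c(0.01, 0.05, 0.07)))
  img_radial <- pseudo_t_image(s$seg, "right", grid = grid, head = fix_head,
                               mode = "radial")
  seg_sub <- preprocess(s$rec, exclude_channels = which(!fix_radial_mask))
  img_sub <- pseudo_t_image(seg_sub, "right", grid = grid, head = fix_head,
                            mode = "triaxial")
  expect_equal(img_radial$values, img_sub$values, tolerance = 1e-12)
})

test_that("beamformer output power grows with planted source amplitude", {
  powers <- vapply(c(2e-9, 5e-9, 1e-8), function(a) {
    p <- generate_participant(1, seed = 51, n_regions = 2, amplitude = a)
    prd <- paradigm(trials_per_block = 2, fs = 200)
    rec <- generate_recording(p, prd, array = fix_array,
                              nm = noise_model(15), seed = 52)
    seg <- preprocess(rec)
    tc <- region_timecourses(seg, "right",
                             p$centroids[p$sm_left, , drop = FALSE], fix_head)
    stats::var(as.numeric(tc))
  }, numeric(1))
  expect_true(all(diff(powers) > 0))
})

test_that("peak repeatability distances follow midpoint geometry", {
  grid <- cbind(seq(0, 0.01, by = 0.002), 0, 0)
  attr(grid, "spacing") <- 0.002
  img_at <- function(peak_idx) {
    v <- rep(0.1, nrow(grid)); v[peak_idx] <- -0.9
    structure(list(grid = grid, values = v, spacing = 0.002),
              class = "source_image")
  }
  # identical images: zero scatter
  rep0 <- peak_and_repeatability(list(img_at(2), img_at(2), img_at(2)))
  expect_equal(rep0$mean_distance_mm, 0)
  # peaks 2 mm apart: each 1 mm from their midpoint
  rep1 <- peak_and_repeatability(list(img_at(1), img_at(2)))
  expect_equal(rep1$mean_distance_mm, 1)
  expect_error(peak_and_repeatability(list(img_at(1))), "two runs")
  expect_error(image_peak(img_at(1), mask = rep(FALSE, nrow(grid))), "empty")
})
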