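test_that("Hilbert envelope recovers amplitudes and modulation", {
  fs <- 200
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  mid <- seq(fs, 9 * fs)
  # constant-amplitude sinusoid: envelope = A within 1% away from edges
  e <- hilbert_envelope(3 * sin(2 * pi * 20 * tt), fs)
  expect_true(all(abs(e[mid] - 3) < 0.03))
  expect_true(all(hilbert_envelope(numeric(100), fs) == 0))
  # AM demodulation oracle
  am <- (1 + 0.5 * sin(2 * pi * 1 * tt)) * sin(2 * pi * 20 * tt)
  e_am <- hilbert_envelope(am, fs)
  expect_gt(stats::cor(e_am[mid], (1 + 0.5 * sin(2 * pi * 1 * tt))[mid]), 0.99)
  # trimming
  e_tr <- hilbert_envelope(am, fs, trim_s = 1)
  expect_equal(length(e_tr), length(tt) - 2 * fs)
  expect_error(hilbert_envelope(c(1, NA, 2), fs), "finite")
})

test_that("time-frequency spectra localize tones and respect windows", {
  fs <- 200
  tt <- seq(0, 12 - 1 / fs, by = 1 / fs)
  bands <- tfs_bands("interference")
  x <- sin(2 * pi * 16.6 * tt)
  sp <- tfs(cbind(x, x), fs, bands)
  rows_lit <- which(bands[, 1] < 16.6 & bands[, 2] > 16.6)
  expect_true(which.max(rowMeans(sp$power)) %in% rows_lit)
  # all-zero input gives an all-zero TFS
  sp0 <- tfs(numeric(length(tt)), fs, bands)
  expect_true(all(sp0$power == 0))
  expect_error(tfs(x, fs, rbind(c(90, 110))), "Nyquist")
  # ERD construction: beta power lower in the active than the control window
  src <- neural_source(1, c(0, 0.03, 0.05), c(1, 0, 0))
  prof <- envelope_profile(src, "right", tt)
  q <- prof * bandpass(stats::rnorm(length(tt)), 13, 30, fs)
  spq <- tfs(q, fs, tfs_bands("interference"))
  beta_mean <- colMeans(spq$power)
  expect_lt(mean(beta_mean[tt >= 2 & tt < 4]), mean(beta_mean[tt >= 5.5 & tt < 7.5]))
})

test_that("orthogonalized AEC removes leakage and keeps nulls null", {
  fs <- 200
  set.seed(61)
  nt <- 120 * fs
  a <- bandpass(stats::rnorm(nt), 13, 30, fs)
  # exact scalar multiple: leakage fully removed
  cm <- aec_connectome(rbind(a, 0.7 * a), fs)
  expect_lt(abs(cm$matrix[1, 2]), 0.05)
  # independent regions: near-zero correlation
  b <- bandpass(stats::rnorm(nt), 13, 30, fs)
  cm2 <- aec_connectome(rbind(a, b), fs)
  expect_lt(abs(cm2$matrix[1, 2]), 0.05)
  # connectome structure invariants
  q <- coupled_region_sim(diag(4) * 0.9 + 0.1, 30, fs, seed = 62)
  cm3 <- aec_connectome(q, fs, condition = "left")
  expect_equal(cm3$matrix, t(cm3$matrix))
  expect_equal(diag(cm3$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(cm3$matrix >= -1 & cm3$matrix <= 1))
  # zero-variance region flagged
  expect_warning(cm4 <- aec_connectome(rbind(a, numeric(nt)), fs),
                 "zero-variance")
  expect_true(is.na(cm4$matrix[1, 2]))
})

test_that("connectivity summaries count unique pairs and node edges", {
  M <- matrix(0.1, 78, 78); diag(M) <- 1
  cs <- connectivity_summaries(M, node = 5)
  expect_equal(cs$n_pairs, 3003L)
  expect_equal(cs$n_edges, 77L)
  expect_equal(cs$whole_brain, 0.1 * 3003)
  expect_equal(cs$node_strength, 0.1 * 77)
  z <- connectivity_summaries(diag(78) * 0, node = 1)
  expect_equal(z$whole_brain, 0); expect_equal(z$node_strength, -0)
  expect_error(connectivity_summaries(M, node = 100), "out of range")
})

test_that("beta modulation measures control-minus-active envelope amplitude", {
  fs <- 100
  env <- rep(1, 12 * fs)
  expect_equal(beta_modulation(env, fs, c(2, 4), c(5, 7)), 0)
  env2 <- c(rep(1, 5 * fs), rep(2, 7 * fs))
  expect_equal(beta_modulation(env2, fs, c(2, 4), c(5, 7)), 1)
  expect_error(beta_modulation(env, fs, c(4, 4), c(5, 7)), "empty")
  # modulation increases with planted suppression depth
  src_at <- function(d) neural_source(1, c(0, 0.03, 0.05), c(1, 0, 0),
                                      erd_depth = c(left = d, right = d),
                                      rebound_gain = c(left = 0.2, right = 0.2))
  tt <- seq(0, 12, by = 1 / fs)[-1]
  mods <- vapply(c(0.2, 0.4, 0.6), function(d)
    beta_modulation(envelope_profile(src_at(d), "right", tt), fs,
                    c(2, 4), c(5, 7)), numeric(1))
  expect_true(all(mods > 0))
  expect_true(all(diff(mods) > 0))
})

test_that("channel SNR is scale invariant and rejects degenerate windows", {
  fs <- 100
  set.seed(63)
  env <- matrix(abs(stats::rnorm(3 * 12 * fs, mean = 2)), 3)
  s1 <- channel_snr(env, fs, c(2, 4), c(5, 7))
  expect_equal(channel_snr(5 * env, fs, c(2, 4), c(5, 7)), s1,
               tolerance = 1e-12)
  flat <- matrix(1, 1, 12 * fs)
  expect_error(channel_snr(flat, fs, c(2, 4), c(5, 7)), "zero envelope")
})

test_that("interference ratio matches the analytic sinusoid-plus-noise value", {
  fs <- 300
  set.seed(64)
  n <- 60 * fs
  tt <- (seq_len(n) - 1) / fs
  # white noise only: flat spectrum, ratio near zero
  expect_lt(abs(interference_ratio(stats::rnorm(n), fs)), 0.2)
  # analytic oracle: with a Hann window of length Nseg, a full-amplitude
  # sinusoid on a bin has peak PSD A^2/2 / (ENBW * df), ENBW = 1.5 bins;
  # one-sided white-noise PSD is 2 sigma^2 / fs
  sigma <- 1
  noise_psd <- 2 * sigma^2 / fs
  df <- 1 / 10                      # 10 s Welch segments
  target <- 10
  A <- sqrt(target * noise_psd * 1.5 * df * 2)
  x <- A * sin(2 * pi * 16.6 * tt) + stats::rnorm(n, sd = sigma)
  r <- interference_ratio(x, fs)
  expect_equal(r, target, tolerance = 0.2 * target)
  # strictly increasing with line amplitude
  rs <- vapply(c(A, 2 * A, 4 * A), function(a)
    interference_ratio(a * sin(2 * pi * 16.6 * tt) +
                         stats::rnorm(n, sd = sigma), fs), numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_error(interference_ratio(stats::rnorm(fs * 5), fs), "too short")
})

test_that("rank-sum tests are exact for small groups and Bonferroni-capped", {
  # fully separated 8 vs 8: two-sided p = 2 / C(16, 8) = 2/12870
  rs <- ranksum_bonferroni(1:8, 101:108)
  expect_equal(rs$p, 2 / 12870, tolerance = 1e-12)
  expect_equal(ranksum_bonferroni(1:8, 101:108, m_tests = 2)$p_corrected,
               2 * 2 / 12870, tolerance = 1e-12)
  # correction caps at 1; complete ties give p = 1
  tie <- ranksum_bonferroni(rep(1, 8), rep(1, 8), m_tests = 5)
  expect_equal(tie$p, 1)
  expect_equal(tie$p_corrected, 1)
  expect_error(ranksum_bonferroni(numeric(0), 1:3), "empty")
  expect_error(ranksum_bonferroni(c(1, NA), 1:3), "missing")
})

test_that("fingerprint comparisons split 120 correlations into 56 and 64", {
  set.seed(65)
  items <- matrix(stats::rnorm(50 * 16), 50)
  fp <- fingerprint_test(items, n_perm = 500, seed = 1)
  expect_equal(length(fp$within), 56L)
  expect_equal(length(fp$between), 64L)
  expect_equal(length(fp$within) + length(fp$between), 120L)
  expect_gt(fp$p, 0); expect_lte(fp$p, 1)
  # identical vectors: zero observed difference, p ~ 1
  v <- stats::rnorm(50)
  fp1 <- fingerprint_test(matrix(v, 50, 16), n_perm = 500, seed = 2)
  expect_equal(fp1$observed, 0)
  expect_equal(fp1$p, 1, tolerance = 1e-12)
  expect_error(fingerprint_test(matrix(0, 5, 10)), "16 run vectors")
})
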