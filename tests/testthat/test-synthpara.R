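test_that("envelope profile has baseline 1, suppression, and a timed rebound", {
  src <- neural_source(1, c(0, 0.03, 0.05), c(1, 0, 0),
                       erd_depth = c(left = 0.4, right = 0.5),
                       rebound_gain = c(left = 0.2, right = 0.2))
  expect_equal(envelope_profile(src, "right", -1), 1)
  expect_equal(envelope_profile(src, "right", -0.001), 1)
  # right-handed rebound window 5.5-7.5 s: fully elevated mid-window
  expect_equal(envelope_profile(src, "right", 6.5), 1.2, tolerance = 1e-12)
  # left-handed rebound is delayed to 9-11 s
  expect_equal(envelope_profile(src, "left", 10), 1.2, tolerance = 1e-12)
  expect_lt(envelope_profile(src, "left", 6.5), 1)   # still writing
  # mean over active window < 1 < mean over rebound window
  tt <- seq(0, 12, by = 0.01)
  prof <- envelope_profile(src, "right", tt)
  expect_lt(mean(prof[tt > 1 & tt < 4]), 1)
  expect_gt(mean(prof[tt > 5.5 & tt < 7.5]), 1)
})

test_that("participants are seeded, distinct, and carry planted structure", {
  p <- generate_participant(1, seed = 3)
  expect_equal(p$n_regions, 78L)
  expect_equal(nrow(p$centroids), 78L)
  expect_identical(generate_participant(1, seed = 3),
                   generate_participant(1, seed = 3))
  # coupling matrices are symmetric with unit diagonal, entries in [0, 1)
  for (cond in c("left", "right")) {
    C <- p$coupling[[cond]]
    expect_equal(C, t(C))
    expect_equal(diag(C), rep(1, 78))
    expect_true(all(C[upper.tri(C)] >= 0 & C[upper.tri(C)] < 1))
  }
  # left-hand condition plants stronger interhemispheric sensorimotor coupling
  expect_gt(p$coupling$left[p$sm_left, p$sm_right],
            p$coupling$right[p$sm_left, p$sm_right])
  # distinct seeds give distinct connectomes
  q <- generate_participant(2, seed = 4)
  r <- stats::cor(p$coupling$left[upper.tri(diag(78))],
                  q$coupling$left[upper.tri(diag(78))])
  expect_lt(r, 0.8)
})

test_that("planted truth is a pure accessor with the paper's lateralization", {
  p <- generate_participant(1, seed = 5)
  tr <- planted_truth(p, "right")
  # right-handed writing: dominant source in the left hemisphere (y > 0)
  expect_equal(tr$dominant_regions, p$sm_left)
  expect_gt(p$centroids[p$sm_left, 2], 0)
  tl <- planted_truth(p, "left")
  expect_equal(sort(tl$dominant_regions), sort(c(p$sm_left, p$sm_right)))
  expect_equal(tl$rebound_window, c(9, 11))
  expect_equal(tr$rebound_window, c(5.5, 7.5))
  # invariant to generation settings (depends only on the participant)
  expect_identical(planted_truth(p, "right"), tr)
})

test_that("recordings have the configured shape, triggers and determinism", {
  p <- generate_participant(1, seed = 6, n_regions = 6)
  prd <- paradigm(trials_per_block = 3, fs = 200)
  rec <- generate_recording(p, prd, array = fix_array, nm = noise_model(15),
                            seed = 7, pad_s = 2)
  expect_equal(nrow(rec$data), 90L)
  expect_equal(ncol(rec$data), (2 * 3 * 12 + 3 * 2) * 200)
  expect_equal(sum(rec$triggers$label == "stimulus"), 6L)
  expect_setequal(unique(rec$triggers$label),
                  c("block_left", "block_right", "stimulus"))
  expect_true(all(is.finite(rec$data)))
  expect_true(all(diff(rec$triggers$sample) >= 0))
  # bitwise determinism under a fixed seed
  rec2 <- generate_recording(p, prd, array = fix_array, nm = noise_model(15),
                             seed = 7, pad_s = 2)
  expect_identical(rec$data, rec2$data)
  expect_identical(rec$triggers, rec2$triggers)
})

test_that("a single noiseless source yields rank-one channel data", {
  p <- generate_participant(1, seed = 8, n_regions = 2)
  # silence region 2: one active dipole with fixed orientation
  p$sources[[2]]$amplitude <- 0
  prd <- paradigm(trials_per_block = 1, fs = 200)
  rec <- generate_recording(p, prd, array = fix_array, nm = NULL, seed = 9)
  sv <- svd(rec$data[, seq(1, ncol(rec$data), by = 7)])$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("channel spectra show a beta hump and an interference line when on", {
  p <- generate_participant(1, seed = 10, n_regions = 8)
  prd <- paradigm(trials_per_block = 3, fs = 300)
  rec <- generate_recording(p, prd, array = fix_array,
                            interference = interference_source(amplitude = 1e-12),
                            nm = noise_model(15), seed = 11)
  ch <- which.max(apply(abs(rec$data), 1, max))
  ps <- welch_psd(rec$data[ch, ], rec$fs)
  inband <- ps$freq >= 13 & ps$freq <= 30
  out_lo <- ps$freq >= 35 & ps$freq <= 60
  line_bin <- which.min(abs(ps$freq - 16.6))
  # 16.6 Hz line dominates its surroundings
  neigh <- which(ps$freq >= 14.5 & ps$freq <= 15.5)
  expect_gt(ps$psd[line_bin], 5 * mean(ps$psd[neigh]))
  # beta hump: in-band PSD (excluding the line) above the out-of-band floor
  beta_bins <- which(inband & abs(ps$freq - 16.6) > 1)
  expect_gt(mean(ps$psd[beta_bins]), 2 * mean(ps$psd[out_lo]))
})

test_that("realized source-level envelope correlation matches planted coupling", {
  target <- rbind(c(1, 0.4), c(0.4, 1))
  q <- coupled_region_sim(target, duration = 240, fs = 240, seed = 12)
  cm <- aec_connectome(q, 240)
  expect_equal(cm$matrix[1, 2], 0.4, tolerance = 0.1)
})
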