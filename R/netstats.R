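# Envelope and spectral analysis, orthogonalized amplitude-envelope-
# correlation connectomes, summary metrics (beta modulation, channel SNR,
# interference ratio), rank-sum contrasts and permutation-based
# fingerprinting statistics.

#' Hilbert (analytic-signal) amplitude envelope
#'
#' Magnitude of the analytic signal computed by the FFT method. Edge
#' transients can be trimmed with \code{trim_s}.
#'
#' @param x numeric vector (finite).
#' @param fs sampling rate, Hz.
#' @param trim_s seconds trimmed from each end (default 0).
#' @return numeric envelope (non-negative); attributes \code{fs} and
#'   \code{trim_s}.
#' @export
hilbert_envelope <- function(x, fs, trim_s = 0) {
  if (any(!is.finite(x))) stop("signal must be finite")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  if (trim_s > 0) {
    k <- round(trim_s * fs)
    if (2 * k >= n) stop("trim exceeds signal length")
    env <- env[(k + 1):(n - k)]
  }
  structure(env, fs = fs, trim_s = trim_s)
}

#' Band sets for time-frequency spectra
#'
#' @param preset "broad" (2 Hz bands, 1 Hz step, 1-48 Hz) or "interference"
#'   (1.5 Hz wide, 0.75 Hz step, 13-30 Hz).
#' @return n x 2 matrix of (lo, hi) band edges in Hz.
#' @export
tfs_bands <- function(preset = c("broad", "interference")) {
  preset <- match.arg(preset)
  if (preset == "broad") {
    lo <- seq(1, 46, by = 1)
    cbind(lo, lo + 2)
  } else {
    lo <- seq(13, 28.5, by = 0.75)
    cbind(lo, lo + 1.5)
  }
}

#' Trial-averaged time-frequency spectrum
#'
#' Per band: band-pass filter, Hilbert envelope, average over trials; rows
#' are concatenated in frequency.
#'
#' @param source_tc samples x trials matrix (or a vector for a single trial).
#' @param fs sampling rate, Hz.
#' @param bands n x 2 matrix of band edges (default \code{tfs_bands("broad")}).
#' @return object of class \code{tfs}: \code{power} (bands x samples matrix
#'   of trial-averaged envelopes), \code{bands}, \code{fs}.
#' @export
tfs <- function(source_tc, fs, bands = tfs_bands("broad")) {
  tc <- as.matrix(source_tc)
  if (any(bands[, 2] >= fs / 2))
    stop("band exceeds the Nyquist rate of the data")
  P <- matrix(0, nrow(bands), nrow(tc))
  for (b in seq_len(nrow(bands))) {
    acc <- numeric(nrow(tc))
    for (k in seq_len(ncol(tc))) {
      xf <- bandpass(tc[, k], bands[b, 1], bands[b, 2], fs)
      acc <- acc + as.numeric(hilbert_envelope(xf, fs))
    }
    P[b, ] <- acc / ncol(tc)
  }
  structure(list(power = P, bands = bands, fs = fs), class = "tfs")
}

#' @export
print.tfs <- function(x, ...) {
  cat(sprintf("tfs: %d bands (%.3g-%.3g Hz) x %d samples at %g Hz\n",
              nrow(x$bands), min(x$bands), max(x$bands), ncol(x$power), x$fs))
  invisible(x)
}

#' Plot a time-frequency spectrum
#' @param x a \code{tfs}.
#' @param ... passed to \code{image}.
#' @export
plot.tfs <- function(x, ...) {
  tt <- (seq_len(ncol(x$power)) - 1) / x$fs
  fc <- rowMeans(x$bands)
  graphics::image(tt, fc, t(x$power), xlab = "time (s)",
                  ylab = "frequency (Hz)", main = "trial-averaged TFS", ...)
  invisible(x)
}

# block-average downsampling (anti-alias for smooth envelopes)
downsample_mean <- function(x, fs, fs_out = 10) {
  k <- round(fs / fs_out)
  n <- floor(length(x) / k)
  colMeans(matrix(x[seq_len(n * k)], k, n))
}

#' Orthogonalized amplitude-envelope-correlation connectome
#'
#' For each unordered region pair, the time course of one region is regressed
#' out of the other (pairwise leakage orthogonalization), both signals'
#' Hilbert envelopes are computed, block-averaged down to \code{fs_out} Hz,
#' and Pearson-correlated; the two regression directions are averaged to
#' keep the matrix symmetric.
#'
#' @param region_tcs regions x time matrix of band-limited time courses.
#' @param fs sampling rate, Hz.
#' @param fs_out envelope sampling rate after downsampling (default 10 Hz).
#' @param labels optional region labels.
#' @param condition optional condition tag.
#' @return object of class \code{connectome}: symmetric \code{matrix} with
#'   unit diagonal, \code{labels}, \code{condition}. Regions with zero
#'   variance get NA edges (flagged in \code{$undefined}).
#' @export
aec_connectome <- function(region_tcs, fs, fs_out = 10, labels = NULL,
                           condition = NULL) {
  X <- as.matrix(region_tcs)
  n <- nrow(X)
  v <- apply(X, 1, stats::var)
  bad <- which(v == 0 | !is.finite(v))
  if (length(bad))
    warning("zero-variance region(s): ", paste(bad, collapse = ", "),
            "; their edges are set to NA")
  env_raw <- matrix(0, n, length(downsample_mean(X[1, ], fs, fs_out)))
  for (r in seq_len(n))
    env_raw[r, ] <- downsample_mean(as.numeric(hilbert_envelope(X[r, ], fs)),
                                    fs, fs_out)
  M <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (i %in% bad || j %in% bad) { M[i, j] <- M[j, i] <- NA_real_; next }
      # one direction: regress region a out of region b; if the residual is
      # numerically null (pure leakage), the orthogonalized correlation is 0
      dir_r <- function(a, b) {
        res <- X[b, ] - X[a, ] * (sum(X[a, ] * X[b, ]) / sum(X[a, ]^2))
        if (stats::var(res) < 1e-12 * stats::var(X[b, ])) return(0)
        er <- downsample_mean(as.numeric(hilbert_envelope(res, fs)), fs, fs_out)
        stats::cor(env_raw[a, ], er)
      }
      M[i, j] <- M[j, i] <- (dir_r(i, j) + dir_r(j, i)) / 2
    }
  }
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(n))
  dimnames(M) <- list(labels, labels)
  structure(list(matrix = M, labels = labels, condition = condition,
                 undefined = bad),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$matrix)
  ut <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf("connectome: %d regions, %d unique pairs%s\n", n,
              n * (n - 1) / 2,
              if (!is.null(x$condition)) paste0(" (", x$condition, ")") else ""))
  cat(sprintf("  edge range [%.3f, %.3f], mean %.3f\n",
              min(ut, na.rm = TRUE), max(ut, na.rm = TRUE),
              mean(ut, na.rm = TRUE)))
  invisible(x)
}

#' Plot a connectome matrix
#' @param x a \code{connectome}.
#' @param ... passed to \code{image}.
#' @export
plot.connectome <- function(x, ...) {
  n <- nrow(x$matrix)
  graphics::image(1:n, 1:n, x$matrix[, n:1], xlab = "region", ylab = "region",
                  main = "AEC connectome", ...)
  invisible(x)
}

#' Vectorize a connectome (upper triangle)
#' @param c a \code{connectome} or square matrix.
#' @return numeric vector of the strictly-upper-triangle entries.
#' @export
connectome_vector <- function(c) {
  M <- if (inherits(c, "connectome")) c$matrix else as.matrix(c)
  M[upper.tri(M)]
}

#' Whole-brain and nodal connectivity summaries
#'
#' @param c a \code{connectome} (or square symmetric matrix).
#' @param node region index for the node strength (e.g. the right
#'   sensorimotor region).
#' @return list: \code{whole_brain} (sum over the n(n-1)/2 unique pairs),
#'   \code{node_strength} (sum of the node's n-1 edges), \code{n_pairs},
#'   \code{n_edges}.
#' @export
connectivity_summaries <- function(c, node = 1L) {
  M <- if (inherits(c, "connectome")) c$matrix else as.matrix(c)
  n <- nrow(M)
  if (node < 1 || node > n) stop("node index out of range")
  list(whole_brain = sum(M[upper.tri(M)]),
       node_strength = sum(M[node, -node]),
       n_pairs = as.integer(round(n * (n - 1) / 2)),
       n_edges = as.integer(n - 1))
}

#' Export a connectome as CSV matrix and edge list
#' @param c a \code{connectome}.
#' @param path_matrix,path_edges output file paths (NULL to skip either).
#' @return invisibly, the edge-list data.frame.
#' @export
write_connectome <- function(c, path_matrix = NULL, path_edges = NULL) {
  M <- c$matrix
  if (!is.null(path_matrix)) utils::write.csv(M, path_matrix)
  ij <- which(upper.tri(M), arr.ind = TRUE)
  edges <- data.frame(regionA = c$labels[ij[, 1]], regionB = c$labels[ij[, 2]],
                      r = M[ij])
  if (!is.null(path_edges)) utils::write.csv(edges, path_edges,
                                             row.names = FALSE)
  invisible(edges)
}

#' Beta-modulation amplitude
#'
#' Signed difference between the mean trial-averaged envelope in the control
#' window and in the active window (rebound-minus-desynchronization
#' convention: positive for the canonical response).
#'
#' @param env trial-averaged envelope (numeric vector over one epoch).
#' @param fs sampling rate, Hz.
#' @param active,control c(start, end) windows in seconds.
#' @return scalar modulation amplitude.
#' @export
beta_modulation <- function(env, fs, active, control) {
  idx_a <- window_samples(active, fs, length(env))
  idx_c <- window_samples(control, fs, length(env))
  mean(env[idx_c]) - mean(env[idx_a])
}

#' Channel-level envelope SNR
#'
#' Per channel: absolute difference of the mean envelope between active and
#' control windows, divided by the envelope standard deviation in the active
#' window.
#'
#' @param env channels x samples matrix of trial-averaged envelopes.
#' @param fs sampling rate, Hz.
#' @param active,control c(start, end) windows in seconds.
#' @return numeric SNR per channel.
#' @export
channel_snr <- function(env, fs, active, control) {
  env <- as.matrix(env)
  idx_a <- window_samples(active, fs, ncol(env))
  idx_c <- window_samples(control, fs, ncol(env))
  sa <- apply(env[, idx_a, drop = FALSE], 1, stats::sd)
  if (any(sa == 0)) stop("zero envelope variance in the active window")
  abs(rowMeans(env[, idx_a, drop = FALSE]) -
        rowMeans(env[, idx_c, drop = FALSE])) / sa
}

#' Trial-averaged band envelope per channel
#'
#' Band-pass filters each channel, computes the Hilbert envelope per trial
#' epoch, and averages over trials.
#'
#' @param seg a \code{segmented_trials}.
#' @param condition condition to use.
#' @param band band edges, Hz (default c(13, 30)).
#' @return channels x samples matrix of trial-averaged envelopes.
#' @export
channel_envelopes <- function(seg, condition, band = c(13, 30)) {
  trials <- seg$trials[[condition]]
  if (is.null(trials)) stop("no trials for condition ", condition)
  nch <- dim(trials)[1]; nsamp <- dim(trials)[2]; ntr <- dim(trials)[3]
  X <- bandpass(matrix(trials, nrow = nch), band[1], band[2], seg$fs)
  # batch Hilbert: one column per (channel, trial) epoch
  M <- matrix(t(X), nrow = nsamp)           # nsamp x (ntr*nch)
  E <- .hilbert_mat(M)
  out <- matrix(0, nch, nsamp)
  for (ch in seq_len(nch))
    out[ch, ] <- rowMeans(E[, ((ch - 1L) * ntr + 1L):(ch * ntr), drop = FALSE])
  out
}

# column-wise analytic-signal envelopes of a matrix (FFT batch)
.hilbert_mat <- function(M) {
  n <- nrow(M)
  H <- stats::mvfft(M)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  Mod(stats::mvfft(H * h, inverse = TRUE) / n)
}

#' Welch power spectral density
#'
#' One-sided Welch PSD with a Hann window and 50\% overlap.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param nperseg segment length in samples (default: 10 s segments, capped
#'   at the record length).
#' @return list with \code{freq} (Hz) and \code{psd} (units^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), round(10 * fs))) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  U <- sum(w^2)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    S <- Mod(stats::fft(seg))^2
    acc <- acc + S[seq_len(nfreq)]
  }
  psd <- acc / (length(starts) * fs * U)
  psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]   # one-sided
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = psd)
}

#' Interference ratio at a line frequency
#'
#' Excess power spectral density at the line frequency relative to its
#' neighbours: (PSD(line) - mean PSD(neighbours)) / mean PSD(neighbours),
#' from a Welch PSD with bins aligned to the narrowest spacing.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param line line frequency, Hz (default 16.6).
#' @param neighbors two neighbouring frequencies (default c(15.5, 17.7)).
#' @return scalar interference ratio.
#' @export
interference_ratio <- function(x, fs, line = 16.6,
                               neighbors = c(15.5, 17.7)) {
  spacing <- min(abs(neighbors - line))
  if (length(x) / fs < 10 / spacing)
    stop("record too short to resolve the line from its neighbours")
  ps <- welch_psd(x, fs)
  at <- function(f) ps$psd[which.min(abs(ps$freq - f))]
  pn <- mean(vapply(neighbors, at, numeric(1)))
  (at(line) - pn) / pn
}

#' Wilcoxon rank-sum test with Bonferroni correction
#'
#' Exact-enumeration two-sided rank-sum p-value for small groups (normal
#' approximation only for n > 10 or in the presence of ties), with
#' Bonferroni-corrected p = min(1, m * p).
#'
#' @param groupA,groupB numeric vectors (no missing values).
#' @param m_tests number of tests in the family (default 1).
#' @return list: \code{statistic} (Mann-Whitney U), \code{p}, \code{p_corrected}.
#' @export
ranksum_bonferroni <- function(groupA, groupB, m_tests = 1) {
  if (!length(groupA) || !length(groupB)) stop("empty group")
  if (anyNA(groupA) || anyNA(groupB)) stop("missing values are not allowed")
  exact <- max(length(groupA), length(groupB)) <= 10 &&
    !any(duplicated(c(groupA, groupB)))
  wt <- suppressWarnings(stats::wilcox.test(groupA, groupB, exact = exact,
                                            correct = !exact))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # degenerate all-tied groups carry no evidence
  list(statistic = unname(wt$statistic), p = p,
       p_corrected = min(1, m_tests * p))
}

#' Permutation fingerprinting test
#'
#' Given run-level feature vectors from two participants (8 runs each), all
#' pairwise Pearson correlations are split into 56 within-participant
#' comparisons (28 unordered run pairs per participant) and 64
#' between-participant comparisons (all 8 x 8 run combinations). The observed
#' statistic is mean(between) - mean(within); the null is generated by
#' randomly permuting the 120 correlation values into sham groups of 64 and
#' 56. The one-sided p-value (within > between, i.e. observed difference
#' negative) includes the +1 correction.
#'
#' @param items 16 feature vectors: a list, or a matrix with 16 columns.
#'   Columns/elements 1-8 are participant 1's runs, 9-16 participant 2's.
#'   \code{connectome} objects are vectorized by their upper triangle.
#' @param n_perm number of random permutations (default 100000).
#' @param seed integer seed.
#' @return object of class \code{fingerprint_result}: \code{within} (56),
#'   \code{between} (64), \code{observed} (between - within mean difference),
#'   \code{p}, \code{n_perm}.
#' @export
fingerprint_test <- function(items, n_perm = 100000, seed = 1L) {
  if (is.list(items)) {
    items <- lapply(items, function(it)
      if (inherits(it, "connectome")) connectome_vector(it)
      else if (inherits(it, "source_image")) it$values
      else as.numeric(it))
    lens <- lengths(items)
    if (length(unique(lens)) != 1) stop("feature vectors differ in length")
    items <- do.call(cbind, items)
  }
  items <- as.matrix(items)
  if (ncol(items) != 16L)
    stop("need exactly 16 run vectors (8 per participant)")
  R <- stats::cor(items)
  w1 <- R[1:8, 1:8][upper.tri(diag(8))]
  w2 <- R[9:16, 9:16][upper.tri(diag(8))]
  within <- c(w1, w2)
  between <- as.numeric(R[1:8, 9:16])
  observed <- mean(between) - mean(within)
  vals <- c(between, within)
  stopifnot(length(vals) == 120L)
  total <- sum(vals)
  count <- local_rng(seed, {
    cnt <- 0L
    for (k in seq_len(n_perm)) {
      s <- sum(vals[sample.int(120L, 64L)])
      sham <- s / 64 - (total - s) / 56
      if (sham <= observed) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(within = within, between = between, observed = observed,
                 p = (1 + count) / (n_perm + 1), n_perm = n_perm),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat("Fingerprinting permutation test\n")
  cat(sprintf("  within : n = %d, mean r = %.3f\n", length(x$within),
              mean(x$within)))
  cat(sprintf("  between: n = %d, mean r = %.3f\n", length(x$between),
              mean(x$between)))
  cat(sprintf("  observed difference (between - within) = %+.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Write a fingerprint result as JSON
#' @param x a \code{fingerprint_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fingerprint <- function(x, path) {
  jsonlite::write_json(list(n_within = length(x$within),
                            n_between = length(x$between),
                            mean_within = mean(x$within),
                            mean_between = mean(x$between),
                            observed = x$observed, p = x$p,
                            n_perm = x$n_perm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
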