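# Source reconstruction: preprocessing, beta-band filtering, regularized
# covariance, LCMV beamforming with Sekihara optimal orientation, pseudo-T
# imaging on a voxel grid, peak repeatability, and virtual electrodes.
# All operations support triaxial (all channels) or radial-only mode.

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filter of the given order per
#' pass; the effective magnitude response is squared.
#'
#' @param x numeric vector, or channels x time matrix (filtered row-wise).
#' @param lo,hi band edges, Hz (default 13 and 30).
#' @param fs sampling rate, Hz (must exceed 2*hi).
#' @param order filter order (default 4).
#' @return filtered data, same shape as \code{x}.
#' @export
bandpass <- function(x, lo = 13, hi = 30, fs, order = 4) {
  if (hi >= fs / 2) stop("upper band edge must be below the Nyquist rate")
  stopifnot(lo > 0, hi > lo)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  filt1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

#' Segment a recording into per-condition trials
#'
#' Removes the per-channel mean, applies an optional channel exclusion list,
#' and cuts trial epochs on stimulus triggers, grouped by block condition.
#'
#' @param rec a \code{recording}.
#' @param exclude_channels integer indices or channel labels to drop.
#' @param trial_s epoch length in seconds (default: the paradigm trial
#'   length stored in the recording).
#' @return object of class \code{segmented_trials}: per condition a
#'   channels x samples x trials array, plus channel metadata.
#' @export
preprocess <- function(rec, exclude_channels = NULL, trial_s = NULL) {
  trig <- rec$triggers
  if (is.null(trig) || nrow(trig) == 0) stop("recording has no triggers")
  if (is.null(trial_s)) trial_s <- rec$paradigm$stimulus_s + rec$paradigm$rest_s
  data <- rec$data - rowMeans(rec$data)
  keep <- seq_len(nrow(data))
  if (!is.null(exclude_channels)) {
    if (is.character(exclude_channels))
      exclude_channels <- match(exclude_channels, rec$array$labels)
    keep <- setdiff(keep, exclude_channels)
  }
  data <- data[keep, , drop = FALSE]
  nsamp <- round(trial_s * rec$fs)
  block_rows <- trig[trig$label %in% c("block_left", "block_right"), ]
  stim <- trig[trig$label == "stimulus", ]
  if (nrow(stim) == 0) stop("recording has no stimulus triggers")
  cond_of <- function(s) {
    prior <- block_rows[block_rows$sample <= s, ]
    if (nrow(prior) == 0) stop("stimulus trigger precedes any block trigger")
    sub("block_", "", prior$label[nrow(prior)])
  }
  conditions <- vapply(stim$sample, cond_of, character(1))
  out <- list()
  for (cond in unique(conditions)) {
    onsets <- stim$sample[conditions == cond]
    onsets <- onsets[onsets + nsamp - 1 <= ncol(data)]
    arr <- array(0, dim = c(nrow(data), nsamp, length(onsets)))
    for (k in seq_along(onsets))
      arr[, , k] <- data[, onsets[k]:(onsets[k] + nsamp - 1)]
    out[[cond]] <- arr
  }
  structure(list(trials = out, fs = rec$fs, channels = keep,
                 labels = rec$array$labels[keep], array = rec$array,
                 trial_s = trial_s),
            class = "segmented_trials")
}

#' @export
print.segmented_trials <- function(x, ...) {
  cat(sprintf("segmented_trials: %d channels, %.1f s epochs at %g Hz\n",
              length(x$channels), x$trial_s, x$fs))
  for (cond in names(x$trials))
    cat(sprintf("  %s: %d trials\n", cond, dim(x$trials[[cond]])[3]))
  invisible(x)
}

#' Regularized data covariance
#'
#' Covariance of concatenated (optionally band-filtered) trials with Tikhonov
#' regularization: C_reg = C + mu * lambda_max(C) * I.
#'
#' @param trials channels x samples x trials array, or channels x time matrix.
#' @param mu regularization fraction of the maximum eigenvalue (default 0.05).
#' @param band optional c(lo, hi) band to filter to before covariance.
#' @param fs sampling rate (required when \code{band} is given).
#' @return object of class \code{covariance_model}: \code{C}, \code{C_reg},
#'   \code{mu}, \code{lambda_max}, \code{rank_deficient}.
#' @export
estimate_covariance <- function(trials, mu = 0.05, band = NULL, fs = NULL) {
  X <- if (length(dim(trials)) == 3L)
    matrix(trials, nrow = dim(trials)[1]) else as.matrix(trials)
  if (ncol(X) < 2 * nrow(X))
    stop("need at least 2x channels of samples for a covariance estimate")
  if (!is.null(band)) {
    if (is.null(fs)) stop("fs required when band filtering")
    X <- bandpass(X, band[1], band[2], fs)
  }
  C <- stats::cov(t(X))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lam <- max(ev)
  rank_def <- min(ev) < 1e-12 * lam
  if (rank_def && mu == 0)
    warning("covariance is rank deficient and no regularization was requested")
  structure(list(C = C, C_reg = C + mu * lam * diag(nrow(C)), mu = mu,
                 lambda_max = lam, rank_deficient = rank_def, band = band),
            class = "covariance_model")
}

#' LCMV beamformer weights with optimal orientation
#'
#' Unit-gain linearly constrained minimum-variance spatial filter. The source
#' orientation within the tangential plane is the one maximizing output SNR:
#' the generalized eigenvector of (L' C^-2 L) eta = lambda (L' C^-1 L) eta
#' with minimum eigenvalue (Sekihara's optimal orientation). Weights are
#' w = C^-1 L eta / (eta' L' C^-1 L eta), so w' L eta = 1.
#'
#' @param cov_model a \code{covariance_model} (its \code{C_reg} is used), or
#'   a positive-definite matrix.
#' @param L channels x 2 leadfield.
#' @return object of class \code{beamformer_solution}: \code{weights},
#'   \code{orientation} (unit 2-vector in the tangential basis),
#'   \code{unit_gain}.
#' @export
lcmv <- function(cov_model, L) {
  C <- if (inherits(cov_model, "covariance_model")) cov_model$C_reg
       else as.matrix(cov_model)
  Ci_L <- solve(C, L)
  A <- crossprod(L, Ci_L)                 # L' C^-1 L
  B <- crossprod(Ci_L)                    # L' C^-2 L
  if (!is.finite(rcond(A)) || rcond(A) < 1e-12)
    stop("singular L' C^-1 L: source orientation is ambiguous at this location")
  eg <- eigen(solve(A, B))
  eta <- Re(eg$vectors[, which.min(Re(eg$values))])
  eta <- eta / sqrt(sum(eta^2))
  denom <- as.numeric(t(eta) %*% A %*% eta)
  w <- as.numeric(Ci_L %*% eta) / denom
  structure(list(weights = w, orientation = eta,
                 unit_gain = abs(sum(w * (L %*% eta)) - 1) < 1e-8),
            class = "beamformer_solution")
}

#' Apply beamformer weights to channel data (virtual electrode)
#'
#' @param sol a \code{beamformer_solution}.
#' @param data channels x time matrix (or channels x samples x trials array).
#' @return source time course(s): vector, or samples x trials matrix.
#' @export
virtual_electrode <- function(sol, data) {
  w <- sol$weights
  if (length(dim(data)) == 3L) {
    apply(data, 3, function(m) as.numeric(crossprod(w, m)))
  } else {
    as.numeric(crossprod(w, as.matrix(data)))
  }
}

# Closed-form minimum-eigenvalue generalized eigenvector of the 2x2 problem
# B eta = lambda A eta (A, B symmetric positive definite): the Sekihara
# optimal orientation. Exact 2x2 arithmetic, avoiding eigen() in voxel loops.
.opt_orientation <- function(A, B) {
  M <- solve(A, B)
  tr <- M[1, 1] + M[2, 2]
  dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  lam <- tr / 2 - sqrt(max(tr^2 / 4 - dt, 0))
  v <- if (abs(M[1, 2]) >= abs(M[2, 1])) c(M[1, 2], lam - M[1, 1])
       else c(lam - M[2, 2], M[2, 1])
  if (sum(abs(v)) < 1e-300) v <- c(1, 0)
  v / sqrt(sum(v^2))
}

# window (seconds, half-open [start, end)) -> sample indices within an epoch
window_samples <- function(window, fs, nsamp) {
  i0 <- floor(window[1] * fs) + 1L
  i1 <- ceiling(window[2] * fs)
  idx <- i0:min(i1, nsamp)
  if (length(idx) == 0 || window[2] <= window[1]) stop("empty analysis window")
  idx
}

# Named window presets (seconds relative to stimulus onset). "imaging" uses
# the 1.5-3.5 s active window against the condition's rebound as control;
# "modulation" uses the beta-modulation windows.
#' Analysis window presets
#' @param preset "imaging" or "modulation".
#' @param condition "left" or "right".
#' @return list with \code{active} and \code{control} c(start, end) windows.
#' @export
window_preset <- function(preset = c("imaging", "modulation"),
                          condition = c("right", "left")) {
  preset <- match.arg(preset)
  condition <- match.arg(condition)
  if (preset == "imaging") {
    list(active = c(1.5, 3.5),
         control = if (condition == "left") c(9, 11) else c(5.5, 7.5))
  } else {
    if (condition == "left") list(active = c(4, 6), control = c(8, 10))
    else list(active = c(2, 4), control = c(5, 7))
  }
}

#' Build an axis-aligned voxel grid inside the head sphere
#'
#' @param head a \code{head_model}.
#' @param spacing voxel spacing in meters (e.g. 0.004 or 0.001).
#' @param bbox optional 2 x 3 matrix (rows: lower, upper corner, meters)
#'   restricting the grid; default: the whole sphere interior.
#' @param max_radius_frac keep voxels with |p - center| below this fraction of
#'   the head radius (default 0.9).
#' @return n x 3 matrix of voxel centers with attributes \code{spacing}.
#' @export
voxel_grid <- function(head, spacing = 0.004, bbox = NULL,
                       max_radius_frac = 0.9) {
  r <- head$radius * max_radius_frac
  if (is.null(bbox))
    bbox <- rbind(head$center - r, head$center + r)
  ax <- lapply(1:3, function(j) seq(bbox[1, j], bbox[2, j], by = spacing))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  colnames(g) <- c("x", "y", "z")
  d <- sqrt(rowSums(sweep(g, 2, head$center, `-`)^2))
  g <- g[d <= r, , drop = FALSE]
  attr(g, "spacing") <- spacing
  g
}

# per-second band power of a windowed source time course across trials
.window_power <- function(tc, idx, fs) {
  # tc: samples x trials; power per second within the window
  sum(tc[idx, ]^2) / (ncol(tc) * length(idx) / fs)
}

#' Pseudo-T source image
#'
#' For each voxel, beamformer weights are computed from the condition's
#' regularized covariance and applied to the band-filtered trials; the image
#' value is the normalized power contrast
#' T = (P_active - P_control) / (P_active + P_control), where P is the
#' projected band power per second in the window. \code{mode = "radial"}
#' restricts every step (covariance, leadfield rows, weights) to the
#' radial-tagged channels.
#'
#' @param seg a \code{segmented_trials} (from \code{preprocess}).
#' @param condition which condition's trials to image.
#' @param windows list with \code{active} and \code{control} windows
#'   (seconds); default: the "imaging" preset for the condition.
#' @param grid voxel positions (n x 3, from \code{voxel_grid}).
#' @param head a \code{head_model}.
#' @param mode "triaxial" (all channels) or "radial".
#' @param band band-pass edges (default c(13, 30)).
#' @param mu covariance regularization (default 0.05).
#' @return object of class \code{source_image}: \code{grid}, \code{values}
#'   (pseudo-T per voxel, in [-1, 1]), \code{mode}, \code{windows}.
#' @export
pseudo_t_image <- function(seg, condition, windows = NULL, grid, head,
                           mode = c("triaxial", "radial"), band = c(13, 30),
                           mu = 0.05) {
  mode <- match.arg(mode)
  if (is.null(windows)) windows <- window_preset("imaging", condition)
  trials <- seg$trials[[condition]]
  if (is.null(trials)) stop("no trials for condition ", condition)
  nsamp <- dim(trials)[2]
  fs <- seg$fs
  idx_a <- window_samples(windows$active, fs, nsamp)
  idx_c <- window_samples(windows$control, fs, nsamp)

  chan_sel <- seq_along(seg$channels)
  if (mode == "radial") {
    mask <- radial_channel_mask(seg$array, head)[seg$channels]
    chan_sel <- which(mask)
  }
  X <- matrix(trials[chan_sel, , ], nrow = length(chan_sel))
  Xf <- bandpass(X, band[1], band[2], fs)
  cv <- estimate_covariance(Xf, mu = mu)
  ntr <- dim(trials)[3]

  # window cross-product matrices: w' S w equals the summed squared
  # beamformer output over the window, so per-voxel power needs only a
  # quadratic form
  win_idx <- function(idx) as.numeric(outer(idx, (seq_len(ntr) - 1L) * nsamp, `+`))
  Xa <- Xf[, win_idx(idx_a), drop = FALSE]
  Xc <- Xf[, win_idx(idx_c), drop = FALSE]
  Sa <- tcrossprod(Xa) / (ntr * length(idx_a) / fs)
  Sc <- tcrossprod(Xc) / (ntr * length(idx_c) / fs)

  Lfull <- leadfield_matrix(seg$array, grid, head)
  full_sel <- seg$channels[chan_sel]
  values <- numeric(nrow(grid))
  Ci <- solve(cv$C_reg)
  Ci2 <- Ci %*% Ci
  for (v in seq_len(nrow(grid))) {
    L <- Lfull[full_sel, (2 * v - 1):(2 * v), drop = FALSE]
    A <- crossprod(L, Ci %*% L)
    B <- crossprod(L, Ci2 %*% L)
    if (rcond(A) < 1e-14) { values[v] <- 0; next }
    eta <- .opt_orientation(A, B)
    w <- as.numeric(Ci %*% (L %*% eta)) / as.numeric(t(eta) %*% A %*% eta)
    Pa <- as.numeric(t(w) %*% Sa %*% w)
    Pc <- as.numeric(t(w) %*% Sc %*% w)
    values[v] <- (Pa - Pc) / (Pa + Pc)
  }
  structure(list(grid = grid, values = values, mode = mode,
                 windows = windows, condition = condition, band = band,
                 spacing = attr(grid, "spacing")),
            class = "source_image")
}

#' @export
print.source_image <- function(x, ...) {
  cat(sprintf("source_image (%s): %d voxels at %.0f mm spacing\n",
              x$mode, nrow(x$grid), 1000 * x$spacing))
  k <- which.max(abs(x$values))
  cat(sprintf("  extremum T = %+.3f at (%.1f, %.1f, %.1f) mm\n",
              x$values[k], 1000 * x$grid[k, 1], 1000 * x$grid[k, 2],
              1000 * x$grid[k, 3]))
  invisible(x)
}

#' Peak voxel of a source image
#'
#' The voxel with the largest absolute pseudo-T (power decreases in the
#' active window give negative T); ties break at the lowest linear index.
#'
#' @param img a \code{source_image}.
#' @param mask optional logical vector over voxels (e.g. a hemisphere mask).
#' @return list with \code{position} (meters), \code{value}, \code{index}.
#' @export
image_peak <- function(img, mask = NULL) {
  vals <- abs(img$values)
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty voxel mask")
    vals[!mask] <- -Inf
  }
  k <- which.max(vals)    # which.max returns the first maximum: low-index ties
  list(position = img$grid[k, ], value = img$values[k], index = k)
}

#' Peak locations and repeatability across runs
#'
#' @param images list of \code{source_image} over runs (same grid).
#' @param mask optional logical hemisphere mask over voxels.
#' @return list with \code{peaks} (runs x 3, meters), \code{mean_location},
#'   \code{distances_mm} (per run, to the cross-run average) and
#'   \code{mean_distance_mm}.
#' @export
peak_and_repeatability <- function(images, mask = NULL) {
  if (length(images) < 2) stop("need at least two runs")
  peaks <- t(vapply(images, function(im) as.numeric(image_peak(im, mask)$position),
                    numeric(3)))
  center <- colMeans(peaks)
  d <- sqrt(rowSums(sweep(peaks, 2, center, `-`)^2)) * 1000
  list(peaks = peaks, mean_location = center,
       distances_mm = d, mean_distance_mm = mean(d))
}

#' Reconstruct regional time courses by beamforming
#'
#' For each region centroid, LCMV weights (optimal tangential orientation)
#' are computed from the condition's regularized covariance and applied to
#' the band-filtered trial data; trials are concatenated in time.
#' \code{mode = "radial"} restricts the whole chain to radial channels.
#'
#' @param seg a \code{segmented_trials}.
#' @param condition condition whose trials to reconstruct.
#' @param positions n x 3 matrix of region centroids (meters).
#' @param head a \code{head_model}.
#' @param mode "triaxial" or "radial".
#' @param band band-pass edges (default c(13, 30); NULL for broadband).
#' @param mu covariance regularization fraction (default 0.05).
#' @return regions x time matrix (trials concatenated), with attribute
#'   \code{"fs"}.
#' @export
region_timecourses <- function(seg, condition, positions, head,
                               mode = c("triaxial", "radial"),
                               band = c(13, 30), mu = 0.05) {
  mode <- match.arg(mode)
  trials <- seg$trials[[condition]]
  if (is.null(trials)) stop("no trials for condition ", condition)
  chan_sel <- seq_along(seg$channels)
  if (mode == "radial")
    chan_sel <- which(radial_channel_mask(seg$array, head)[seg$channels])
  X <- matrix(trials[chan_sel, , ], nrow = length(chan_sel))
  if (!is.null(band)) X <- bandpass(X, band[1], band[2], seg$fs)
  cv <- estimate_covariance(X, mu = mu)
  Ci <- solve(cv$C_reg)
  full_sel <- seg$channels[chan_sel]
  Lfull <- leadfield_matrix(seg$array, positions, head)
  out <- matrix(0, nrow(positions), ncol(X))
  for (r in seq_len(nrow(positions))) {
    L <- Lfull[full_sel, (2 * r - 1):(2 * r), drop = FALSE]
    A <- crossprod(L, Ci %*% L)
    B <- crossprod(L, (Ci %*% Ci) %*% L)
    eta <- .opt_orientation(A, B)
    w <- as.numeric(Ci %*% (L %*% eta)) / as.numeric(t(eta) %*% A %*% eta)
    out[r, ] <- as.numeric(crossprod(w, X))
  }
  attr(out, "fs") <- seg$fs
  out
}

#' Export a source image as a flat CSV (x, y, z, T)
#' @param img a \code{source_image}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_source_image <- function(img, path) {
  df <- data.frame(x = img$grid[, 1], y = img$grid[, 2], z = img$grid[, 3],
                   t = img$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a source image slice
#'
#' Simple base-graphics map of the voxel layer nearest \code{z}.
#' @param x a \code{source_image}.
#' @param z slice height (meters); default: the peak's z.
#' @param ... passed to \code{image}.
#' @export
plot.source_image <- function(x, z = NULL, ...) {
  if (is.null(z)) z <- image_peak(x)$position[3]
  zs <- sort(unique(round(x$grid[, 3], 10)))
  zsel <- zs[which.min(abs(zs - z))]
  sel <- abs(x$grid[, 3] - zsel) < 1e-9
  xs <- sort(unique(x$grid[sel, 1])); ys <- sort(unique(x$grid[sel, 2]))
  m <- matrix(NA_real_, length(xs), length(ys))
  ix <- match(round(x$grid[sel, 1], 10), round(xs, 10))
  iy <- match(round(x$grid[sel, 2], 10), round(ys, 10))
  m[cbind(ix, iy)] <- x$values[sel]
  graphics::image(xs * 1000, ys * 1000, m, xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("pseudo-T, z = %.0f mm (%s)", zsel * 1000,
                                 x$mode), ...)
  invisible(x)
}
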