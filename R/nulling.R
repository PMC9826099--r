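# Background-field mapping and nulling. The remnant quasi-static field inside
# the shielded enclosure is modelled as three uniform components plus five
# independent linear gradients. Moving the helmet through this field while
# tracking its pose makes the eight coefficients identifiable from the
# motion-induced signal changes at a small subset of sensors; DC coil currents
# then cancel the fitted field. A 60 Hz proportional-integral loop on a
# stationary reference array compensates slow drift.

# deterministic small-integer seed derivation (stays below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483647)
}

#' Generate a smooth field-mapping head-motion trace
#'
#' A 120 Hz pose trajectory exercising all six degrees of freedom: each Euler
#' angle and translation component follows a seeded two-tone sinusoid with
#' distinct frequencies, so the design matrix of the subsequent harmonic fit
#' has full column rank.
#'
#' @param duration seconds (> 0; default 60).
#' @param amp_deg rotation amplitude about each axis, degrees (default 10).
#' @param amp_m translation amplitude along each axis, meters (default 0.05).
#' @param fs motion sampling rate, Hz (default 120).
#' @param seed integer seed.
#' @return a \code{motion_trace}.
#' @export
generate_mapping_motion <- function(duration = 60, amp_deg = 10, amp_m = 0.05,
                                    fs = 120, seed = 1L) {
  stopifnot(duration > 0)
  if (amp_deg == 0 && amp_m == 0)
    warning("zero motion amplitudes: the field-map fit will be rank deficient")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  pars <- local_rng(seed, list(
    f1 = stats::runif(6, 0.05, 0.15), f2 = stats::runif(6, 0.17, 0.30),
    ph1 = stats::runif(6, 0, 2 * pi), ph2 = stats::runif(6, 0, 2 * pi)))
  dof <- sapply(1:6, function(k) {
    0.6 * sin(2 * pi * pars$f1[k] * t + pars$ph1[k]) +
      0.4 * sin(2 * pi * pars$f2[k] * t + pars$ph2[k])
  })
  ang <- dof[, 1:3, drop = FALSE] * (amp_deg * pi / 180)
  trn <- dof[, 4:6, drop = FALSE] * amp_m
  poses <- lapply(seq_len(n), function(i) {
    rigid_transform(euler_rotation(ang[i, 1], ang[i, 2], ang[i, 3]), trn[i, ])
  })
  motion_trace(t, poses, fs)
}

#' Pick the field-mapping sensor subset
#'
#' Returns indices of \code{n} sensors closest to canonical front, back, top,
#' left and right helmet directions (the layout used for the background fit).
#'
#' @param array a \code{sensor_array}.
#' @param n subset size (default 5).
#' @return integer vector of sensor indices.
#' @export
choose_nulling_subset <- function(array, n = 5) {
  dirs <- rbind(c(1, 0, 0.4), c(-1, 0, 0.4), c(0, 0, 1),
                c(0, 1, 0.4), c(0, -1, 0.4), c(0.7, 0.7, 0.4),
                c(0.7, -0.7, 0.4), c(-0.7, 0.7, 0.4))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  u <- array$positions / sqrt(rowSums(array$positions^2))
  picked <- integer(0)
  for (k in seq_len(min(n, nrow(dirs)))) {
    sc <- as.numeric(u %*% dirs[k, ])
    sc[picked] <- -Inf
    picked <- c(picked, which.max(sc))
  }
  picked
}

# Per-sample moved positions / axis vectors of the subset channels.
# Returns list of matrices (rows = time) per channel, flattened as long
# vectors for design-matrix assembly.
.moved_geometry <- function(array, motion, sensors) {
  nt <- length(motion$poses)
  ns <- length(sensors)
  # flatten poses once: columns R11,R21,R31,R12,... (column-major), then t
  Rf <- matrix(0, nt, 9); Tr <- matrix(0, nt, 3)
  for (it in seq_len(nt)) {
    Rf[it, ] <- as.numeric(motion$poses[[it]]$rotation)
    Tr[it, ] <- motion$poses[[it]]$translation
  }
  P <- array(0, dim = c(nt, 3, 3 * ns))   # positions per channel
  A <- array(0, dim = c(nt, 3, 3 * ns))   # axis unit vectors per channel
  for (s in seq_len(ns)) {
    p0 <- array$positions[sensors[s], ]
    pm <- matrix(0, nt, 3)
    for (i in 1:3)
      pm[, i] <- Rf[, i] * p0[1] + Rf[, i + 3] * p0[2] + Rf[, i + 6] * p0[3] +
        Tr[, i]
    for (ax in 1:3) {
      a0 <- array$axes[, ax, sensors[s]]
      ch <- 3L * (s - 1L) + ax
      P[, , ch] <- pm
      for (i in 1:3)
        A[, i, ch] <- Rf[, i] * a0[1] + Rf[, i + 3] * a0[2] + Rf[, i + 6] * a0[3]
    }
  }
  list(P = P, A = A)
}

#' Simulate field-mapping channel data
#'
#' Channel signals seen by the subset sensors while the helmet moves through
#' a quasi-static background field. OPMs are field-zeroed at the start pose,
#' so each channel reports the change a(t).B(p(t)) - a(0).B(p(0)) plus white
#' noise at the motion rate.
#'
#' @param bg a \code{background_field} (nT, nT/m).
#' @param array a \code{sensor_array}.
#' @param motion a \code{motion_trace}.
#' @param sensors integer indices of the subset sensors.
#' @param nm a \code{noise_model} or NULL.
#' @param gm a \code{gain_model} or NULL (gain error from the per-channel
#'   quasi-static step).
#' @return channels x time matrix in tesla (channels = 3 per subset sensor).
#' @export
map_channels <- function(bg, array, motion, sensors, nm = NULL, gm = NULL) {
  geo <- .moved_geometry(array, motion, sensors)
  nt <- dim(geo$P)[1]; nch <- dim(geo$P)[3]
  y <- matrix(0, nch, nt)
  for (ch in seq_len(nch)) {
    Bv <- background_at(bg, geo$P[, , ch])           # nt x 3, nT
    y[ch, ] <- rowSums(geo$A[, , ch] * Bv) * 1e-9    # tesla
  }
  y <- y - y[, 1]
  step_nT <- apply(abs(y), 1, max) * 1e9
  synthesize_channels(y, gm = gm, nm = nm, fs = motion$fs, step_nT = step_nT)
}

#' Fit the eight-coefficient harmonic field model to mapping data
#'
#' Linear least squares over the model
#' y_i(t) = a_i(t)' (b0 + G p_i(t)) + c_i, where a_i(t), p_i(t) are the moved
#' axis and position of channel i and c_i a per-channel DC offset (absorbing
#' the unobservable absolute field of zeroed OPMs). Offsets are projected out
#' by within-channel centering; the eight field coefficients are then solved
#' by QR.
#'
#' @param channels channels x time matrix, tesla (one row per subset channel,
#'   sensor-major, axes x, y, z).
#' @param motion a \code{motion_trace} time-aligned with \code{channels}.
#' @param array a \code{sensor_array}.
#' @param sensors integer indices of the subset sensors used.
#' @return object of class \code{field_map_fit}: \code{coefficients} (named
#'   8-vector: Bx, By, Bz in nT; Gxx, Gyy, Gxy, Gxz, Gyz in nT/m),
#'   \code{offsets_nT}, \code{residual_rms_nT}, \code{condition_number}.
#' @export
fit_field_map <- function(channels, motion, array, sensors) {
  channels <- as.matrix(channels)
  nch <- nrow(channels); nt <- ncol(channels)
  if (nch != 3L * length(sensors))
    stop("channel count must be 3 per subset sensor")
  if (nt != length(motion$poses))
    stop("channel data and motion trace are not time-aligned")
  geo <- .moved_geometry(array, motion, sensors)
  X <- matrix(0, nch * nt, 8L)
  yv <- numeric(nch * nt)
  rowofs <- 0L
  ch_means_X <- matrix(0, nch, 8L)
  ch_means_y <- numeric(nch)
  for (ch in seq_len(nch)) {
    a <- geo$A[, , ch]; p <- geo$P[, , ch]
    Xi <- cbind(a[, 1], a[, 2], a[, 3],
                a[, 1] * p[, 1] - a[, 3] * p[, 3],
                a[, 2] * p[, 2] - a[, 3] * p[, 3],
                a[, 1] * p[, 2] + a[, 2] * p[, 1],
                a[, 1] * p[, 3] + a[, 3] * p[, 1],
                a[, 2] * p[, 3] + a[, 3] * p[, 2])
    yi <- channels[ch, ] * 1e9                       # nT
    ch_means_X[ch, ] <- colMeans(Xi)
    ch_means_y[ch] <- mean(yi)
    X[rowofs + seq_len(nt), ] <- sweep(Xi, 2, ch_means_X[ch, ], `-`)
    yv[rowofs + seq_len(nt)] <- yi - ch_means_y[ch]
    rowofs <- rowofs + nt
  }
  sv <- svd(X, nu = 0, nv = 8)
  names8 <- c("Bx", "By", "Bz", "Gxx", "Gyy", "Gxy", "Gxz", "Gyz")
  if (sv$d[1] == 0 || sv$d[8] / sv$d[1] < 1e-10) {
    bad <- which(abs(sv$v[, 8]) > 0.3)
    stop("rank-deficient mapping design: components not identifiable: ",
         paste(names8[bad], collapse = ", "))
  }
  fit <- stats::lm.fit(X, yv)
  beta <- stats::setNames(as.numeric(fit$coefficients), names8)
  offsets <- ch_means_y - as.numeric(ch_means_X %*% beta)
  structure(list(coefficients = beta,
                 offsets_nT = offsets,
                 residual_rms_nT = sqrt(mean(fit$residuals^2)),
                 condition_number = sv$d[1] / sv$d[8],
                 n_samples = nt, n_channels = nch),
            class = "field_map_fit")
}

#' @export
coef.field_map_fit <- function(object, ...) object$coefficients

#' @export
print.field_map_fit <- function(x, ...) {
  cat("Harmonic background-field fit (8 coefficients)\n")
  cat(sprintf("  uniform   |B0| = %.4g nT  (Bx %.3g, By %.3g, Bz %.3g)\n",
              sqrt(sum(x$coefficients[1:3]^2)), x$coefficients[1],
              x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  gradient  |G|  = %.4g nT/m\n",
              sqrt(sum(x$coefficients[4:8]^2))))
  cat(sprintf("  residual rms %.3g nT, design condition number %.3g\n",
              x$residual_rms_nT, x$condition_number))
  invisible(x)
}

#' Background field implied by a fit
#' @param fit a \code{field_map_fit}.
#' @return a \code{background_field} with the fitted coefficients.
#' @export
fitted_field <- function(fit) {
  background_field(fit$coefficients[1:3], fit$coefficients[4:8])
}

#' Compensation currents cancelling a fitted field
#'
#' I = -calibration^{-1} . coefficients, so that the coil output exactly
#' opposes the fitted field.
#'
#' @param fit a \code{field_map_fit} (or named 8-vector of coefficients).
#' @param coils a \code{coil_system}.
#' @return length-8 current vector.
#' @export
compensation_currents <- function(fit, coils) {
  coeff <- if (inherits(fit, "field_map_fit")) fit$coefficients else fit
  stopifnot(length(coeff) == 8L)
  if (kappa(coils$calibration, exact = TRUE) > 1e12 ||
      abs(det(coils$calibration)) < 1e-300)
    stop("coil calibration matrix is singular; cannot compute currents")
  as.numeric(solve(coils$calibration, -coeff))
}

#' Run the iterative static-field nulling procedure
#'
#' Simulates the mapping-movement / fit / compensation cycle: for each
#' iteration a fresh 60 s mapping motion is generated, subset channels are
#' synthesized under the current effective field, the eight-coefficient model
#' is fitted, and opposing DC coil currents are added. A final mapping pass
#' measures the residual field.
#'
#' @param env the true environmental \code{background_field}.
#' @param coils a \code{coil_system}.
#' @param array a \code{sensor_array}.
#' @param gm a \code{gain_model} or NULL.
#' @param nm a \code{noise_model} or NULL (its seed is re-derived per pass).
#' @param iterations number of nulling iterations (>= 1; default 2).
#' @param seed integer seed for motion and noise.
#' @param mapping_duration mapping-movement duration, seconds (default 60).
#' @param amp_deg,amp_m mapping-motion amplitudes (default 10 deg, 0.05 m).
#' @param sensors subset sensor indices (default
#'   \code{choose_nulling_subset(array)}).
#' @return object of class \code{nulling_report}: pre/post coefficient norms,
#'   per-iteration fitted coefficients and currents, and the true residual
#'   field.
#' @export
run_nulling <- function(env, coils, array, gm = NULL, nm = NULL,
                        iterations = 2, seed = 1L, mapping_duration = 60,
                        amp_deg = 10, amp_m = 0.05, sensors = NULL) {
  stopifnot(iterations >= 1)
  if (is.null(sensors)) sensors <- choose_nulling_subset(array)
  currents <- numeric(8)
  bg_eff <- env
  iters <- list()
  pre <- NULL
  for (it in seq_len(iterations + 1L)) {
    motion <- generate_mapping_motion(mapping_duration, amp_deg, amp_m,
                                      seed = derive_seed(seed, it))
    nm_it <- if (is.null(nm)) NULL else
      noise_model(nm$density_fT, derive_seed(seed, 1000 + it))
    ch <- map_channels(bg_eff, array, motion, sensors, nm = nm_it, gm = gm)
    fit <- fit_field_map(ch, motion, array, sensors)
    if (it == 1L) pre <- field_norms(fitted_field(fit))
    if (it > iterations) {                 # final mapping: measure only
      iters[[it]] <- list(fit = fit, currents = currents)
      break
    }
    dI <- compensation_currents(fit, coils)
    currents <- currents + dI
    bg_eff <- add_fields(env, coil_output(coils, currents))
    iters[[it]] <- list(fit = fit, currents = currents)
  }
  post_fit <- iters[[iterations + 1L]]$fit
  structure(list(
    pre_norms = pre,
    post_norms = field_norms(fitted_field(post_fit)),
    true_residual = bg_eff,
    true_residual_norms = field_norms(bg_eff),
    currents = currents,
    iterations = iters,
    seed = seed),
    class = "nulling_report")
}

#' @export
print.nulling_report <- function(x, ...) {
  cat("Static-field nulling report\n")
  cat(sprintf("  pre : |B0| = %.3g nT, |G| = %.3g nT/m\n",
              x$pre_norms[1], x$pre_norms[2]))
  cat(sprintf("  post: |B0| = %.3g nT, |G| = %.3g nT/m  (%d iterations)\n",
              x$post_norms[1], x$post_norms[2], length(x$iterations) - 1L))
  invisible(x)
}

#' Default reference array for dynamic stabilization
#'
#' Four dual-axis magnetometers behind the participant, separated ~40 cm in z
#' but sharing x and y coordinates (so only z-varying gradients are
#' identifiable, in addition to the uniform components).
#'
#' @return list with \code{positions} (4 x 3) and \code{axes} (3 x 2 x 4;
#'   each sensor measures the y and z field components).
#' @export
default_reference_array <- function() {
  z <- c(-0.20, -0.065, 0.065, 0.20)
  positions <- cbind(rep(-0.45, 4), rep(0.02, 4), z)
  axes <- array(0, dim = c(3, 2, 4))
  for (k in 1:4) axes[, , k] <- cbind(c(0, 1, 0), c(0, 0, 1))
  # tilt two sensors slightly so Bx is observable
  rot <- euler_rotation(0, 0.3, 0)
  axes[, , 2] <- rot %*% axes[, , 2]
  axes[, , 4] <- rot %*% axes[, , 4]
  list(positions = positions, axes = axes)
}

#' PI stabilizer state
#'
#' @param kp proportional gain (unitless).
#' @param ki integral gain (1/s). Defaults give near-critical damping with
#'   the 3 Hz reference low-pass.
#' @param cutoff_hz reference low-pass cutoff (default 3).
#' @param rate_hz controller update rate (default 60; must exceed 2x cutoff).
#' @return object of class \code{stabilizer_state}.
#' @export
stabilizer_state <- function(kp = 0.5, ki = 6 * pi, cutoff_hz = 3,
                             rate_hz = 60) {
  if (rate_hz <= 2 * cutoff_hz)
    stop("update rate must exceed twice the low-pass cutoff")
  structure(list(kp = kp, ki = ki, cutoff_hz = cutoff_hz, rate_hz = rate_hz,
                 integral = numeric(6)),
            class = "stabilizer_state")
}

# controllable coefficient vector: (Bx, By, Bz, Gxz, Gyz, Gzz)
.stab_field <- function(u) {
  background_field(u[1:3], c(-u[6] / 2, -u[6] / 2, 0, u[4], u[5]))
}

# reference design matrix mapping (Bx,By,Bz,Gxz,Gyz,Gzz) -> 8 ref channels
.reference_design <- function(ref) {
  M <- matrix(0, 8, 6)
  row <- 0L
  for (s in 1:4) {
    p <- ref$positions[s, ]
    for (ax in 1:2) {
      a <- ref$axes[, ax, s]
      row <- row + 1L
      M[row, ] <- c(a[1], a[2], a[3],
                    a[1] * p[3] + a[3] * p[1],
                    a[2] * p[3] + a[3] * p[2],
                    a[3] * p[3] - (a[1] * p[1] + a[2] * p[2]) / 2)
    }
  }
  M
}

#' Dynamic stabilization of slow background-field drift
#'
#' Discrete 60 Hz proportional-integral loop: the eight reference channels are
#' low-pass filtered at 3 Hz, the six compensable field components (three
#' uniform, three z-varying gradients) are estimated by least squares, and
#' opposing coil fields are applied at the next tick.
#'
#' @param reference reference array (see \code{default_reference_array}).
#' @param drift function(t) returning a \code{background_field}: the
#'   uncompensated drift at time t.
#' @param state a \code{stabilizer_state}.
#' @param duration simulated seconds.
#' @param nm optional \code{noise_model} for the reference channels.
#' @return object of class \code{stabilization_trace}: times, residual
#'   controllable components (6 x time, nT and nT/m), applied compensation.
#' @export
dynamic_stabilization <- function(reference = default_reference_array(),
                                  drift, state = stabilizer_state(),
                                  duration = 10, nm = NULL) {
  fs <- state$rate_hz
  dt <- 1 / fs
  n <- round(duration * fs)
  M <- .reference_design(reference)
  Minv <- solve(crossprod(M), t(M))
  alpha <- 1 - exp(-2 * pi * state$cutoff_hz * dt)
  u <- numeric(6)                       # applied compensation components
  yf <- numeric(8)
  est_prev <- numeric(6)
  resid <- matrix(0, 6, n)
  applied <- matrix(0, 6, n)
  times <- (seq_len(n) - 1L) * dt
  sigma <- if (is.null(nm)) 0 else noise_sigma(nm, fs) * 1e9   # nT
  noise <- if (sigma > 0)
    local_rng(nm$seed, matrix(stats::rnorm(8L * n, sd = sigma), 8L)) else NULL
  ori8 <- matrix(0, 8, 3); pos8 <- matrix(0, 8, 3)
  row <- 0L
  for (s in 1:4) for (ax in 1:2) {
    row <- row + 1L
    ori8[row, ] <- reference$axes[, ax, s]
    pos8[row, ] <- reference$positions[s, ]
  }
  for (i in seq_len(n)) {
    d <- drift(times[i])
    dvec <- c(d$b0, d$g[4], d$g[5], -d$g[1] - d$g[2])
    resid[, i] <- dvec - u
    applied[, i] <- u
    # residual field seen by the reference sensors under current compensation
    bg_res <- add_fields(d, .stab_field(-u))
    y <- rowSums(ori8 * background_at(bg_res, pos8))
    if (!is.null(noise)) y <- y + noise[, i]
    yf <- yf + alpha * (y - yf)
    est <- as.numeric(Minv %*% yf)
    # velocity-form PI: u accumulates Kp * d(est) + Ki * est * dt
    u <- u + state$kp * (est - if (i > 1L) est_prev else est) +
      state$ki * est * dt
    est_prev <- est
    if (any(!is.finite(u)) || max(abs(u)) > 1e6) {
      cond <- simpleError("dynamic stabilization diverged (unstable gains)")
      cond$last_stable <- list(t = times[i], compensation = applied[, i],
                               residual = resid[, i])
      stop(cond)
    }
  }
  structure(list(times = times, residual = resid, applied = applied,
                 state = state),
            class = "stabilization_trace")
}

#' @export
print.stabilization_trace <- function(x, ...) {
  n <- ncol(x$residual)
  tail_idx <- max(1L, floor(0.8 * n)):n
  cat("Dynamic stabilization trace\n")
  cat(sprintf("  duration %.1f s at %g Hz; final |uniform residual| = %.4g nT\n",
              max(x$times), x$state$rate_hz,
              sqrt(sum(x$residual[1:3, n]^2))))
  cat(sprintf("  steady-state rms of uniform residual: %.4g nT\n",
              sqrt(mean(x$residual[1:3, tail_idx]^2))))
  invisible(x)
}
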