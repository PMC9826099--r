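# Synthetic-data generator: paradigm timing, condition-dependent beta-band
# source dynamics (event-related desynchronization during writing, delayed
# post-movement rebound for the non-dominant hand), participant-specific
# region geometry and planted envelope-coupling structure, and full triaxial
# recordings combining neural fields, background-field movement artifact,
# environmental interference, OPM gain error and white sensor noise.

#' Handwriting paradigm definition
#'
#' @param n_blocks blocks per experiment (default 2: one per hand).
#' @param trials_per_block trials per block (default 20).
#' @param stimulus_s word-presentation period, seconds (default 5).
#' @param rest_s rest period, seconds (default 7).
#' @param fs channel sampling rate, Hz (default 1200).
#' @param conditions block conditions (default c("left", "right")).
#' @return object of class \code{paradigm}.
#' @export
paradigm <- function(n_blocks = 2, trials_per_block = 20, stimulus_s = 5,
                     rest_s = 7, fs = 1200,
                     conditions = c("left", "right")) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1, stimulus_s > 0, rest_s > 0,
            fs > 0, length(conditions) == n_blocks)
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 stimulus_s = stimulus_s, rest_s = rest_s, fs = fs,
                 conditions = conditions,
                 trial_s = stimulus_s + rest_s),
            class = "paradigm")
}

#' Beta-band neural source
#'
#' @param region region index.
#' @param position dipole position, meters (inside the head sphere).
#' @param orientation tangential moment direction (unit 3-vector).
#' @param amplitude baseline dipole moment, ampere-meters (default 5 nA.m).
#' @param erd_depth named fraction per condition: envelope suppression during
#'   writing (0 = none, 1 = full).
#' @param rebound_gain named fraction per condition: envelope elevation in
#'   the post-movement rebound window.
#' @param erd_window,rebound_window named lists of c(start, end) windows in
#'   seconds since stimulus onset. The rebound is delayed for left-handed
#'   (non-dominant) writing: 9-11 s versus 5.5-7.5 s for right-handed.
#' @param band carrier band, Hz (default c(13, 30)).
#' @return object of class \code{neural_source}.
#' @export
neural_source <- function(region = 1L, position, orientation,
                          amplitude = 5e-9,
                          erd_depth = c(left = 0.4, right = 0.4),
                          rebound_gain = c(left = 0.25, right = 0.25),
                          erd_window = list(left = c(0.3, 8.3),
                                            right = c(0.3, 4.8)),
                          rebound_window = list(left = c(9, 11),
                                                right = c(5.5, 7.5)),
                          band = c(13, 30)) {
  stopifnot(all(erd_depth >= 0), all(erd_depth <= 1), all(rebound_gain >= 0))
  structure(list(region = region, position = as.numeric(position),
                 orientation = .normalize(as.numeric(orientation)),
                 amplitude = amplitude, erd_depth = erd_depth,
                 rebound_gain = rebound_gain, erd_window = erd_window,
                 rebound_window = rebound_window, band = band),
            class = "neural_source")
}

# raised-cosine window: 0 outside [a, b], 1 on the plateau, cosine ramps of
# width `ramp` inside the edges
.rc_window <- function(t, a, b, ramp = 0.4) {
  out <- numeric(length(t))
  inside <- t > a & t < b
  out[inside] <- 1
  up <- t > a & t < a + ramp
  out[up] <- 0.5 - 0.5 * cos(pi * (t[up] - a) / ramp)
  dn <- t > b - ramp & t < b
  out[dn] <- 0.5 - 0.5 * cos(pi * (b - t[dn]) / ramp)
  out
}

#' Trial envelope profile of a source
#'
#' Amplitude multiplier over a trial: 1 at baseline, suppressed to
#' (1 - erd_depth) during writing, elevated to (1 + rebound_gain) in the
#' condition's post-movement rebound window, with smooth raised-cosine
#' transitions.
#'
#' @param src a \code{neural_source}.
#' @param condition "left" or "right".
#' @param t seconds since stimulus onset (vectorized; t < 0 gives 1).
#' @return amplitude multiplier(s).
#' @export
envelope_profile <- function(src, condition, t) {
  ew <- src$erd_window[[condition]]
  rw <- src$rebound_window[[condition]]
  1 - src$erd_depth[[condition]] * .rc_window(t, ew[1], ew[2]) +
    src$rebound_gain[[condition]] * .rc_window(t, rw[1], rw[2])
}

# canonical sensorimotor directions (head frame: x anterior, y left,
# z superior); motor cortex slightly posterior and superior
.sm_dir <- function(side) {
  d <- c(-0.25, if (side == "left") 0.55 else -0.55, 0.80)
  .normalize(d)
}

#' Generate a synthetic participant
#'
#' Seeded random region geometry on the source sphere (78 regions, a proxy
#' for a cortical parcellation), with the first two regions fixed near the
#' left and right sensorimotor cortices; a planted per-condition envelope-
#' coupling (connectome) matrix with elevated bilateral sensorimotor coupling
#' for left-handed writing; and per-condition lateralization of the
#' event-related desynchronization (right-handed writing dominated by the
#' left motor region, left-handed writing bilateral).
#'
#' @param id participant identifier.
#' @param seed integer seed: distinct seeds give distinct fingerprints.
#' @param n_regions number of regions (default 78).
#' @param head a \code{head_model}.
#' @param source_radius radius of the source shell, meters (default 0.065).
#' @param amplitude sensorimotor baseline dipole moment, A.m (default
#'   5 nA.m).
#' @return object of class \code{participant}.
#' @export
generate_participant <- function(id = 1L, seed = 1L, n_regions = 78,
                                 head = head_model(), source_radius = 0.065,
                                 amplitude = 5e-9) {
  stopifnot(n_regions >= 2)
  local_rng(seed, {
    sm_left <- 1L; sm_right <- 2L
    dirs <- matrix(0, n_regions, 3)
    dirs[sm_left, ] <- .sm_dir("left")
    dirs[sm_right, ] <- .sm_dir("right")
    n_other <- n_regions - 2L
    if (n_other > 0) {
      i <- seq_len(n_other)
      # lattice over the upper 3/4 of the sphere (cortical shell proxy)
      cosu <- 1 - (i - 0.5) / n_other * 1.5
      sinu <- sqrt(pmax(0, 1 - cosu^2))
      phi <- i * pi * (3 - sqrt(5))
      d <- cbind(sinu * cos(phi), sinu * sin(phi), cosu)
      d <- d + matrix(stats::rnorm(3 * n_other, sd = 0.08), n_other)
      dirs[-(1:2), ] <- d / sqrt(rowSums(d^2))
    }
    radii <- source_radius * exp(stats::rnorm(n_regions, sd = 0.03))
    centroids <- dirs * radii + matrix(head$center, n_regions, 3, byrow = TRUE)
    # random tangential orientations
    orientations <- t(vapply(seq_len(n_regions), function(r) {
      tp <- .tangential_pair(dirs[r, ])
      th <- stats::runif(1, 0, 2 * pi)
      as.numeric(tp %*% c(cos(th), sin(th)))
    }, numeric(3)))
    amplitudes <- rep(0.4 * amplitude, n_regions) *
      exp(stats::rnorm(n_regions, sd = 0.15))
    amplitudes[c(sm_left, sm_right)] <- amplitude *
      exp(stats::rnorm(2, sd = 0.05))
    # lateralization: dominant (right) hand -> left motor region;
    # non-dominant (left) hand -> bilateral
    depth <- matrix(0, n_regions, 2, dimnames = list(NULL, c("left", "right")))
    depth[sm_left, ] <- c(0.40, 0.50)
    depth[sm_right, ] <- c(0.40, 0.12)
    depth <- depth * exp(matrix(stats::rnorm(2 * n_regions, sd = 0.08),
                                n_regions))
    depth[depth > 0.95] <- 0.95
    rebound <- 0.6 * depth
    # planted connectome targets: weak random background coupling plus a
    # strong interhemispheric sensorimotor edge for left-handed writing
    base <- matrix(0, n_regions, n_regions)
    base[upper.tri(base)] <- stats::runif(n_regions * (n_regions - 1) / 2,
                                          0.01, 0.10)
    base <- base + t(base); diag(base) <- 1
    coupling <- list(left = base, right = base)
    # left-handed (non-dominant) writing recruits a broader bilateral
    # network: globally elevated coupling, a stronger right-sensorimotor
    # node, and a strong interhemispheric sensorimotor edge
    coupling$left <- coupling$left + 0.03
    coupling$left[sm_right, ] <- coupling$left[sm_right, ] + 0.06
    coupling$left[, sm_right] <- coupling$left[sm_right, ]
    coupling$left[sm_left, sm_right] <- coupling$left[sm_right, sm_left] <- 0.40
    coupling$right[sm_left, sm_right] <- coupling$right[sm_right, sm_left] <- 0.15
    diag(coupling$left) <- 1
    sources <- lapply(seq_len(n_regions), function(r)
      neural_source(r, centroids[r, ], orientations[r, ],
                    amplitude = amplitudes[r],
                    erd_depth = c(left = unname(depth[r, "left"]),
                                  right = unname(depth[r, "right"])),
                    rebound_gain = c(left = unname(rebound[r, "left"]),
                                     right = unname(rebound[r, "right"]))))
    structure(list(id = id, seed = seed, n_regions = n_regions,
                   centroids = centroids, orientations = orientations,
                   amplitudes = amplitudes, sources = sources,
                   coupling = coupling, head = head,
                   sm_left = sm_left, sm_right = sm_right),
              class = "participant")
  })
}

#' @export
print.participant <- function(x, ...) {
  cat(sprintf("participant %s: %d regions (seed %d)\n", x$id, x$n_regions,
              x$seed))
  cat(sprintf("  planted sensorimotor coupling: left %.2f, right %.2f\n",
              x$coupling$left[x$sm_left, x$sm_right],
              x$coupling$right[x$sm_left, x$sm_right]))
  invisible(x)
}

#' Planted ground truth for a condition
#'
#' Pure accessor: invariant to any noise, background or interference
#' settings used when generating recordings.
#'
#' @param p a \code{participant}.
#' @param condition "left" or "right".
#' @return list: \code{dominant_regions} (indices), \code{peak_position}
#'   (meters; the left motor region for right-handed writing),
#'   \code{erd_window}, \code{rebound_window}, \code{connectome} (planted
#'   target matrix), \code{erd_depth} per region.
#' @export
planted_truth <- function(p, condition = c("right", "left")) {
  condition <- match.arg(condition)
  depth <- vapply(p$sources, function(s) s$erd_depth[[condition]], numeric(1))
  dominant <- if (condition == "right") p$sm_left else c(p$sm_left, p$sm_right)
  src <- p$sources[[p$sm_left]]
  list(dominant_regions = dominant,
       peak_position = p$centroids[if (condition == "right") p$sm_left
                                   else p$sm_right, ],
       erd_window = src$erd_window[[condition]],
       rebound_window = src$rebound_window[[condition]],
       connectome = p$coupling[[condition]],
       erd_depth = depth)
}

# smooth standardized Gaussian processes (rows), low-pass filtered white
# noise; cutoff in Hz
.smooth_gp <- function(n, nt, fs, cutoff = 0.5) {
  bf <- signal::butter(2, min(0.99, cutoff / (fs / 2)), type = "low")
  Z <- matrix(stats::rnorm(n * nt), n, nt)
  for (r in seq_len(n)) {
    z <- as.numeric(signal::filtfilt(bf, Z[r, ]))
    Z[r, ] <- (z - mean(z)) / stats::sd(z)
  }
  Z
}

# correlated log-normal envelopes: rows have (approximately) the modulator
# correlation matrix C; each envelope has mean ~1
.coupled_envelopes <- function(C, nt, fs, sigma = 0.35) {
  n <- nrow(C)
  Z <- .smooth_gp(n, nt, fs)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-8)
  A <- eg$vectors %*% (sqrt(vals) * t(eg$vectors))
  M <- A %*% Z
  exp(sigma * M - sigma^2 / 2)
}

# Calibration of the coupling -> realized amplitude-envelope-correlation map.
# The shared-drive log-normal construction attenuates envelope correlation
# through the stochastic carrier; the attenuation slope is measured once by
# simulation (internal fixed seed) and cached for the session.
.triaxmeg_cache <- new.env(parent = emptyenv())

#' Envelope-coupling calibration slope
#'
#' Realized amplitude-envelope correlation (Hilbert envelope of a beta-band
#' carrier modulated by coupled log-normal envelopes, block-averaged to
#' 10 Hz) per unit modulator correlation. Measured by a short seeded
#' simulation and cached for the session.
#'
#' @param sigma log-envelope depth (default 0.35, the generator's default).
#' @param fs simulation rate (default 300 Hz).
#' @param duration simulated seconds (default 240).
#' @return scalar slope in (0, 1].
#' @export
coupling_calibration <- function(sigma = 0.35, fs = 300, duration = 240) {
  key <- sprintf("cal_%g_%g_%g", sigma, fs, duration)
  if (!is.null(.triaxmeg_cache[[key]])) return(.triaxmeg_cache[[key]])
  slope <- local_rng(900001L, {
    nt <- round(duration * fs)
    ws <- c(0.3, 0.6, 0.9)
    rs <- numeric(length(ws))
    for (k in seq_along(ws)) {
      C <- rbind(c(1, ws[k]), c(ws[k], 1))
      E <- .coupled_envelopes(C, nt, fs, sigma)
      q <- E * rbind(bandpass(stats::rnorm(nt), 13, 30, fs),
                     bandpass(stats::rnorm(nt), 13, 30, fs))
      e1 <- downsample_mean(as.numeric(hilbert_envelope(q[1, ], fs)), fs, 10)
      e2 <- downsample_mean(as.numeric(hilbert_envelope(q[2, ], fs)), fs, 10)
      rs[k] <- stats::cor(e1, e2)
    }
    sum(rs * ws) / sum(ws^2)
  })
  .triaxmeg_cache[[key]] <- slope
  slope
}

# planted target matrix -> modulator correlation matrix (PSD-projected)
.coupling_to_modulator <- function(target, slope) {
  W <- target / slope
  diag(W) <- 1
  W[W > 0.97] <- 0.97
  eg <- eigen(W, symmetric = TRUE)
  if (min(eg$values) < 1e-6) {
    W <- eg$vectors %*% (pmax(eg$values, 1e-6) * t(eg$vectors))
    d <- sqrt(diag(W))
    W <- W / outer(d, d)
  }
  W
}

# trial-locked task motion: forward (x) translation and looking-down
# rotation about z during writing, trial-locked, at 120 Hz
.task_motion <- function(total_s, par, condition_of_t, fs_motion = 120,
                         amp_m = 0.03, amp_deg = 8, seed = 1L) {
  n <- round(total_s * fs_motion)
  t <- (seq_len(n) - 1L) / fs_motion
  prof <- condition_of_t(t)   # writing-intensity profile in [0, 1]
  wander <- local_rng(seed, .smooth_gp(2, n, fs_motion, cutoff = 0.2)) * 0.1
  rz <- (prof + wander[1, ]) * amp_deg * pi / 180
  tx <- (prof + wander[2, ]) * amp_m
  poses <- lapply(seq_len(n), function(i)
    rigid_transform(euler_rotation(0, 0, rz[i]), c(tx[i], 0, 0)))
  motion_trace(t, poses, fs_motion)
}

# small polynomial rolling hash of a serialized object (hex string);
# arithmetic kept below 2^53 so it is exact in doubles
config_hash <- function(x) {
  s <- utf8ToInt(paste(utils::capture.output(utils::str(x, digits.d = 12)),
                       collapse = "\n"))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", as.integer(h))
}

#' Generate a full synthetic triaxial recording
#'
#' Composes the signal chain: band-limited Gaussian carriers modulated by
#' trial-locked envelope profiles and planted cross-region envelope coupling,
#' projected through the (quasi-statically moving) array's leadfields;
#' background-field movement artifact; sinusoidal environmental
#' interference; Lorentzian gain error; white sensor noise; embedded
#' triggers.
#'
#' @param p a \code{participant}.
#' @param prd a \code{paradigm}.
#' @param array a \code{sensor_array} (default 30-sensor helmet).
#' @param env a \code{background_field} (nT) or NULL for none.
#' @param interference an \code{interference_source} or NULL.
#' @param gm a \code{gain_model} or NULL.
#' @param nm a \code{noise_model} or NULL.
#' @param motion "task" for trial-locked handwriting motion, a
#'   \code{motion_trace}, or NULL for a static helmet. Head and helmet move
#'   as one rigid body, so motion affects the background-field artifact and
#'   gain error but not the neural leadfields.
#' @param seed integer seed (carriers, envelopes, noise, motion wander).
#' @param block_order condition order of the blocks (default the paradigm's
#'   conditions).
#' @param pad_s padding before, between and after blocks, seconds (default 2).
#' @param sigma log-envelope modulation depth (default 0.35).
#' @param return_sources also return the true per-region source time courses
#'   (memory-heavy for long recordings).
#' @return object of class \code{recording}.
#' @export
generate_recording <- function(p, prd = paradigm(),
                               array = build_helmet_array(30),
                               env = NULL, interference = NULL, gm = NULL,
                               nm = noise_model(), motion = NULL, seed = 1L,
                               block_order = NULL, pad_s = 2, sigma = 0.35,
                               return_sources = FALSE) {
  fs <- prd$fs
  if (is.null(block_order)) block_order <- prd$conditions
  stopifnot(length(block_order) == prd$n_blocks)
  trial_n <- round(prd$trial_s * fs)
  block_n <- trial_n * prd$trials_per_block
  pad_n <- round(pad_s * fs)
  total_n <- pad_n + prd$n_blocks * (block_n + pad_n)
  total_s <- total_n / fs
  nch <- n_channels(array)
  nreg <- p$n_regions

  # trigger table and per-sample condition/trial phase
  trig <- data.frame(sample = integer(0), label = character(0),
                     stringsAsFactors = FALSE)
  cond_id <- integer(total_n)          # 0 = baseline, else block index
  tphase <- rep(-1, total_n)           # seconds since stimulus onset
  at <- pad_n + 1L
  for (b in seq_len(prd$n_blocks)) {
    trig <- rbind(trig, data.frame(sample = at,
                                   label = paste0("block_", block_order[b])))
    for (k in seq_len(prd$trials_per_block)) {
      on <- at + (k - 1L) * trial_n
      trig <- rbind(trig, data.frame(sample = on, label = "stimulus"))
    }
    idx <- at:(at + block_n - 1L)
    cond_id[idx] <- b
    tphase[idx] <- ((idx - at) %% trial_n) / fs
    at <- at + block_n + pad_n
  }

  slope <- coupling_calibration(sigma)
  seeds <- list(envelope = derive_seed(seed, 1), carrier = derive_seed(seed, 2),
                motion = derive_seed(seed, 3), noise = derive_seed(seed, 4))

  # per-region envelopes: coupling depends on condition; build blockwise
  E <- matrix(1, nreg, total_n)
  for (b in seq_len(prd$n_blocks)) {
    W <- .coupling_to_modulator(p$coupling[[block_order[b]]], slope)
    idx <- which(cond_id == b)
    E[, idx] <- local_rng(derive_seed(seeds$envelope, b),
                          .coupled_envelopes(W, length(idx), fs, sigma))
  }
  # trial-locked ERD / rebound profile per region
  for (r in seq_len(nreg)) {
    src <- p$sources[[r]]
    prof <- rep(1, total_n)
    for (b in seq_len(prd$n_blocks)) {
      idx <- which(cond_id == b)
      prof[idx] <- envelope_profile(src, block_order[b], tphase[idx])
    }
    E[r, ] <- E[r, ] * prof * src$amplitude
  }

  # band-limited carriers and source time courses
  Q <- local_rng(seeds$carrier, {
    Z <- matrix(stats::rnorm(nreg * total_n), nreg, total_n)
    bandpass(Z, p$sources[[1]]$band[1], p$sources[[1]]$band[2], fs)
  })
  # normalize carriers to unit rms so amplitudes are in A.m
  Q <- Q / sqrt(rowMeans(Q^2))
  Q <- Q * E
  rm(E)

  # motion trace
  if (identical(motion, "task")) {
    writing <- function(tt) {
      smp <- pmin(pmax(round(tt * fs) + 1L, 1L), total_n)
      ph <- tphase[smp]
      ifelse(ph >= 0, .rc_window(ph, 0.2, 4.8, ramp = 0.8), 0)
    }
    motion <- .task_motion(total_s, p, writing, seed = seeds$motion)
  }

  # project sources through the leadfields. Helmet and head move together as
  # one rigid body, so the head-to-sensor geometry -- and with it the
  # leadfield of the isotropic spherical conductor -- is invariant under the
  # motion; movement enters the data only through the background field (the
  # helmet sweeping through a spatially fixed remnant field) and gain error.
  G <- matrix(0, nch, nreg)
  Lm <- leadfield_matrix(array, p$centroids, p$head)
  for (r in seq_len(nreg)) {
    basis <- source_tangential_basis(p$centroids[r, ], p$head)
    eta <- as.numeric(crossprod(basis, p$orientations[r, ]))
    G[, r] <- Lm[, (2 * r - 1):(2 * r)] %*% eta
  }
  data <- G %*% Q
  sources_out <- if (return_sources) Q else NULL
  rm(Q)

  # background-field movement artifact (quasi-static, per channel)
  step_nT <- 0
  if (!is.null(env) && !is.null(motion)) {
    nt_m <- length(motion$poses)
    art <- matrix(0, nch, nt_m)
    geo <- .moved_geometry(array, motion, seq_len(nrow(array$positions)))
    for (ch in seq_len(nch)) {
      Bv <- background_at(env, geo$P[, , ch])
      art[ch, ] <- rowSums(geo$A[, , ch] * Bv) * 1e-9
    }
    art <- art - art[, 1]
    step_nT <- apply(abs(art), 1, max) * 1e9
    tq <- (seq_len(total_n) - 1L) / fs
    for (ch in seq_len(nch)) {
      data[ch, ] <- data[ch, ] +
        stats::approx(motion$timestamps, art[ch, ], xout = tq, rule = 2)$y
    }
  }

  if (!is.null(interference)) {
    tt <- (seq_len(total_n) - 1L) / fs
    data <- data + interference_at(interference, array, tt)
  }

  nm_rec <- if (is.null(nm)) NULL else noise_model(nm$density_fT, seeds$noise)
  data <- synthesize_channels(data, gm = gm, nm = nm_rec, fs = fs,
                              step_nT = step_nT)

  cfg <- list(participant = p$id, participant_seed = p$seed,
              n_regions = nreg, paradigm = unclass(prd),
              block_order = block_order, pad_s = pad_s, seed = seed,
              sigma = sigma,
              env = if (is.null(env)) NULL else unclass(env),
              interference = if (is.null(interference)) NULL
                             else unclass(interference)[c("frequency",
                                                          "amplitude")],
              noise_fT = if (is.null(nm)) 0 else nm$density_fT)
  structure(list(data = data, fs = fs, triggers = trig, motion = motion,
                 array = array, paradigm = prd, participant_id = p$id,
                 sources = sources_out,
                 provenance = list(schema = "triaxmeg-recording-1",
                                   seed = seed, seeds = seeds,
                                   config = cfg,
                                   config_hash = config_hash(cfg))),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  %d triggers (%d stimuli); config hash %s\n",
              nrow(x$triggers), sum(x$triggers$label == "stimulus"),
              x$provenance$config_hash))
  invisible(x)
}
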