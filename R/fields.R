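# Forward models: current dipole in a homogeneous conducting sphere (Sarvas
# closed form), quasi-static background field (uniform + linear gradient),
# biplanar coil system, and sinusoidal environmental interference.

MU0 <- 4 * pi * 1e-7

#' Current dipole
#'
#' @param position 3-vector, meters, strictly inside the head sphere.
#' @param moment 3-vector, ampere-meters (nominal scale nA.m).
#' @return object of class \code{dipole}.
#' @export
dipole <- function(position, moment) {
  stopifnot(length(position) == 3L, length(moment) == 3L)
  structure(list(position = as.numeric(position), moment = as.numeric(moment)),
            class = "dipole")
}

#' Magnetic field of a current dipole in a conducting sphere
#'
#' Closed-form (Sarvas) external field of a current dipole embedded in a
#' homogeneous spherical conductor, including the volume-current
#' contribution. Linear in the dipole moment; a purely radial moment produces
#' zero external field.
#'
#' @param d a \code{dipole}; position strictly inside the sphere.
#' @param at observation point(s): 3-vector or n x 3 matrix, strictly outside
#'   the sphere.
#' @param head a \code{head_model}.
#' @return n x 3 matrix of field vectors in tesla.
#' @export
dipole_field <- function(d, at, head) {
  at <- matrix(as.numeric(at), ncol = 3L)
  r0 <- d$position - head$center
  if (sqrt(sum(r0^2)) >= head$radius)
    stop("dipole must lie strictly inside the head sphere")
  r <- sweep(at, 2, head$center, `-`)
  rn <- sqrt(rowSums(r^2))
  if (any(rn <= head$radius))
    stop("observation points must lie strictly outside the head sphere")
  a_vec <- sweep(r, 2, r0, `-`)
  an <- sqrt(rowSums(a_vec^2))
  r0_dot_r <- as.numeric(r %*% r0)
  a_dot_r <- rowSums(a_vec * r)
  F_ <- an * (rn * an + rn^2 - r0_dot_r)
  c1 <- an^2 / rn + a_dot_r / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + a_dot_r / an
  gradF <- r * c1 - outer(c2, r0)
  qxr0 <- pracma_cross(d$moment, r0)
  q_dot <- as.numeric(r %*% qxr0)
  B <- (matrix(qxr0, nrow(at), 3, byrow = TRUE) * F_ - gradF * q_dot) *
    (MU0 / (4 * pi * F_^2))
  B
}

# Free-space field of a point current element (Biot-Savart of Q at r0):
# B(r) = mu0/4pi * Q x (r - r0) / |r - r0|^3. Used as an oracle for the
# radial-component identity of the conducting-sphere solution.
#' Free-space (primary-current) dipole field
#' @param d a \code{dipole}.
#' @param at observation point(s), 3-vector or n x 3 matrix.
#' @return n x 3 matrix, tesla.
#' @export
dipole_field_freespace <- function(d, at) {
  at <- matrix(as.numeric(at), ncol = 3L)
  rel <- sweep(at, 2, d$position, `-`)
  dist3 <- rowSums(rel^2)^1.5
  qx <- t(apply(rel, 1, function(v) pracma_cross(d$moment, v)))
  qx * (MU0 / (4 * pi)) / dist3
}

# Tangential source basis at a position inside the sphere: (polar, azimuthal)
# unit vectors orthogonal to the local radial direction. Degenerate at the
# sphere center: a deterministic fallback pair in the xy-plane is used and a
# message is emitted.
source_tangential_basis <- function(source_pos, head) {
  u <- source_pos - head$center
  un <- sqrt(sum(u^2))
  if (un < 1e-9) {
    message("source at sphere center: using fallback tangential basis (x, y)")
    return(cbind(c(1, 0, 0), c(0, 1, 0)))
  }
  .tangential_pair(u / un)
}

#' Leadfield of a source location for a sensor array
#'
#' Channel responses to unit current dipoles along the two source-tangential
#' directions (radial sources are externally silent in a spherical
#' conductor, so only the tangential pair is modelled).
#'
#' @param array a \code{sensor_array}.
#' @param source_pos 3-vector, meters, inside the sphere.
#' @param head a \code{head_model}.
#' @return channels x 2 matrix, tesla per ampere-meter. Attribute
#'   \code{"basis"} holds the 3 x 2 tangential source basis.
#' @export
leadfield <- function(array, source_pos, head) {
  basis <- source_tangential_basis(source_pos, head)
  ori <- channel_orientations(array)
  pos <- array$positions
  idx <- array$sensor_id
  L <- matrix(0, n_channels(array), 2L)
  for (j in 1:2) {
    B <- dipole_field(dipole(source_pos, basis[, j]), pos, head)
    L[, j] <- rowSums(ori * B[idx, , drop = FALSE])
  }
  attr(L, "basis") <- basis
  L
}

# Leadfields for many source positions at once: returns channels x (2 n_src)
# matrix with columns (src1-t1, src1-t2, src2-t1, ...).
#' Leadfields for a set of source positions
#' @param array a \code{sensor_array}.
#' @param source_pos n x 3 matrix of positions inside the sphere.
#' @param head a \code{head_model}.
#' @return channels x (2n) matrix, tesla per ampere-meter.
#' @export
leadfield_matrix <- function(array, source_pos, head) {
  source_pos <- matrix(as.numeric(source_pos), ncol = 3L)
  n <- nrow(source_pos)
  out <- matrix(0, n_channels(array), 2L * n)
  for (k in seq_len(n)) {
    out[, (2 * k - 1):(2 * k)] <- leadfield(array, source_pos[k, ], head)
  }
  out
}

#' Quasi-static background field model
#'
#' Uniform field plus linear gradient, parameterized by the three uniform
#' components and the five independent components of the symmetric trace-free
#' gradient tensor (Gxx, Gyy, Gxy, Gxz, Gyz; Gzz = -Gxx - Gyy).
#'
#' @param b0 3-vector, nT.
#' @param g 5-vector, nT/m, ordered (Gxx, Gyy, Gxy, Gxz, Gyz).
#' @return object of class \code{background_field}.
#' @export
background_field <- function(b0 = c(0, 0, 0), g = c(0, 0, 0, 0, 0)) {
  stopifnot(length(b0) == 3L, length(g) == 5L)
  structure(list(b0 = as.numeric(b0), g = as.numeric(g)),
            class = "background_field")
}

#' Gradient tensor of a background field
#' @param bg a \code{background_field}.
#' @return 3x3 symmetric trace-free matrix, nT/m.
#' @export
gradient_tensor <- function(bg) {
  g <- bg$g
  rbind(c(g[1], g[3], g[4]),
        c(g[3], g[2], g[5]),
        c(g[4], g[5], -g[1] - g[2]))
}

#' Evaluate a background field
#'
#' @param bg a \code{background_field}.
#' @param at 3-vector or n x 3 matrix of positions (meters).
#' @return n x 3 matrix, nT.
#' @export
background_at <- function(bg, at) {
  at <- matrix(as.numeric(at), ncol = 3L)
  G <- gradient_tensor(bg)
  sweep(at %*% t(G), 2, bg$b0, `+`)
}

#' Euclidean norms of the background-field coefficients
#' @param bg a \code{background_field}.
#' @return named vector: \code{b0_nT} (norm of the three uniform components)
#'   and \code{g_nT_per_m} (norm of the five gradient components).
#' @export
field_norms <- function(bg) {
  c(b0_nT = sqrt(sum(bg$b0^2)), g_nT_per_m = sqrt(sum(bg$g^2)))
}

#' Biplanar coil system
#'
#' Eight coils producing the three uniform field components and five gradient
#' components; \code{calibration[i, j]} is the coefficient i (nT or nT/m)
#' produced per unit current in coil j.
#'
#' @param calibration invertible 8x8 matrix.
#' @return object of class \code{coil_system} with the calibration, its
#'   condition number, and coefficient names.
#' @export
coil_system <- function(calibration = diag(8)) {
  calibration <- as.matrix(calibration)
  stopifnot(all(dim(calibration) == c(8L, 8L)))
  kap <- kappa(calibration, exact = TRUE)
  structure(list(calibration = calibration, condition_number = kap,
                 coefficients = c("Bx", "By", "Bz",
                                  "Gxx", "Gyy", "Gxy", "Gxz", "Gyz")),
            class = "coil_system")
}

#' Default coil system with seeded off-diagonal leakage
#'
#' Identity-like calibration with a given fraction of random off-diagonal
#' leakage, exercising the matrix-inversion path of current computation.
#'
#' @param leakage off-diagonal scale as a fraction of the diagonal (default
#'   0.05).
#' @param seed integer seed for the leakage draw.
#' @return a \code{coil_system}.
#' @export
default_coil_system <- function(leakage = 0.05, seed = 1L) {
  M <- local_rng(seed, {
    E <- matrix(stats::rnorm(64, sd = leakage), 8, 8)
    diag(E) <- 0
    diag(8) + E
  })
  coil_system(M)
}

#' Field coefficients produced by coil currents
#' @param coils a \code{coil_system}.
#' @param currents length-8 numeric.
#' @return \code{background_field} produced by the coils.
#' @export
coil_output <- function(coils, currents) {
  stopifnot(length(currents) == 8L)
  coeff <- as.numeric(coils$calibration %*% currents)
  background_field(coeff[1:3], coeff[4:8])
}

#' Add two background fields coefficient-wise
#' @param a,b \code{background_field} objects.
#' @return their superposition.
#' @export
add_fields <- function(a, b) background_field(a$b0 + b$b0, a$g + b$g)

#' Environmental interference source
#'
#' A sinusoidal line source. Its spatial pattern is either that of a distant
#' magnetic dipole (\code{position}, \code{orientation}) or a uniform field
#' along \code{direction}.
#'
#' @param frequency Hz (> 0); default 16.6.
#' @param amplitude peak field at the helmet, tesla.
#' @param position far-dipole position (meters) or NULL for a uniform
#'   pattern.
#' @param orientation dipole moment direction (far-dipole pattern).
#' @param direction field direction (uniform pattern).
#' @return object of class \code{interference_source}.
#' @export
interference_source <- function(frequency = 16.6, amplitude = 1e-12,
                                position = c(5, 0, 0),
                                orientation = c(0, 0, 1),
                                direction = NULL) {
  stopifnot(frequency > 0)
  structure(list(frequency = frequency, amplitude = amplitude,
                 position = position, orientation = orientation,
                 direction = direction),
            class = "interference_source")
}

# static (unit-time) channel pattern of an interference source
interference_pattern <- function(src, array) {
  ori <- channel_orientations(array)
  if (!is.null(src$direction)) {
    pat <- as.numeric(ori %*% .normalize(src$direction))
  } else {
    pos <- channel_positions(array)
    rel <- sweep(pos, 2, src$position, `-`)
    rn <- sqrt(rowSums(rel^2))
    rhat <- rel / rn
    m <- .normalize(src$orientation)
    mdot <- as.numeric(rhat %*% m)
    Bdip <- (3 * rhat * mdot - matrix(m, nrow(rel), 3, byrow = TRUE)) / rn^3
    pat <- rowSums(ori * Bdip)
  }
  scale <- max(abs(pat))
  if (scale == 0) return(pat)
  pat / scale * src$amplitude
}

#' Interference field time course per channel
#'
#' @param src an \code{interference_source}.
#' @param array a \code{sensor_array}.
#' @param t numeric vector of times (seconds).
#' @return channels x length(t) matrix, tesla.
#' @export
interference_at <- function(src, array, t) {
  pat <- interference_pattern(src, array)
  outer(pat, sin(2 * pi * src$frequency * t))
}

#' Round-trip a background field / coil system to a JSON config block
#' @param x a \code{background_field} or \code{coil_system}.
#' @return JSON string.
#' @export
field_config_json <- function(x) {
  if (inherits(x, "background_field")) {
    jsonlite::toJSON(list(type = "background_field", b0_nT = x$b0,
                          g_nT_per_m = x$g), digits = NA, auto_unbox = TRUE)
  } else if (inherits(x, "coil_system")) {
    jsonlite::toJSON(list(type = "coil_system",
                          calibration = x$calibration), digits = NA,
                     auto_unbox = TRUE)
  } else stop("unsupported object")
}

#' Parse a JSON config block written by \code{field_config_json}
#' @param txt JSON string.
#' @return the reconstructed object.
#' @export
field_config_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  switch(obj$type,
         background_field = background_field(obj$b0_nT, obj$g_nT_per_m),
         coil_system = coil_system(obj$calibration),
         stop("unknown config type: ", obj$type))
}

# Run expr with a local, restored RNG state under the given seed.
local_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
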