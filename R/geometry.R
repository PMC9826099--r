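# Sensor-array geometry: helmet construction, rigid-body motion, sphere
# fitting, and radial/tangential decomposition.
#
# Head coordinate convention (used everywhere in this package): right-handed,
# origin at the head-sphere center, x anterior, y left, z superior; all
# positions in meters.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation numeric length-3 translation (meters).
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rotation matrix is not orthogonal (R'R != I within 1e-10)")
  if (abs(det(rotation) - 1) > 1e-10)
    stop("rotation matrix is not proper (det != +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' \code{compose_transforms(p1, p2)} returns the transform equivalent to
#' applying \code{p2} first and then \code{p1}.
#'
#' @param p1,p2 \code{rigid_transform} objects.
#' @return A \code{rigid_transform}.
#' @export
compose_transforms <- function(p1, p2) {
  rigid_transform(p1$rotation %*% p2$rotation,
                  as.numeric(p1$rotation %*% p2$translation) + p1$translation)
}

#' Rotation matrix from Euler angles
#'
#' Intrinsic rotations about x, y, z (in that order), angles in radians.
#' @param rx,ry,rz rotation angles (radians).
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(rx = 0, ry = 0, rz = 0) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Spherical head model
#'
#' @param center numeric length-3 (meters).
#' @param radius positive scalar (meters).
#' @return An object of class \code{head_model}.
#' @export
head_model <- function(center = c(0, 0, 0), radius = 0.09) {
  stopifnot(length(center) == 3L, radius > 0)
  structure(list(center = as.numeric(center), radius = radius),
            class = "head_model")
}

.normalize <- function(v) v / sqrt(sum(v^2))

# Orthonormal tangential pair completing a radial unit vector u into a
# right-handed basis (t1, t2, u). Reference axis switched when u is nearly
# parallel to z to keep the construction well conditioned.
.tangential_pair <- function(u) {
  ref <- if (abs(u[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  t1 <- .normalize(pracma_cross(ref, u))
  t2 <- pracma_cross(u, t1)
  cbind(t1, t2)
}

# 3-vector cross product (kept local; no dependency needed for this)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a triaxial helmet sensor array
#'
#' Places \code{n_sensors} triaxial magnetometers quasi-uniformly (Fibonacci
#' lattice, deterministic) on a spherical cap of the helmet surface. Each
#' sensor carries an orthonormal axis triad: two tangential axes (channel tags
#' "x", "y") and one outward radial axis (tag "z"), giving three channels per
#' sensor.
#'
#' @param n_sensors number of triaxial sensors (>= 1).
#' @param scalp_radius scalp sphere radius in meters (default 0.09).
#' @param standoff sensor cell standoff from the scalp in meters (default
#'   0.0065).
#' @param coverage list with elements \code{center} (unit direction of the cap
#'   axis) and \code{half_angle} (cap half-angle, radians). Default: a cap
#'   about +z with half-angle 1.1 rad, covering the vertex and both
#'   sensorimotor regions.
#' @param head optional \code{head_model}; defaults to a sphere of radius
#'   \code{scalp_radius} at the origin.
#' @return An object of class \code{sensor_array} with elements
#'   \code{positions} (n x 3, meters), \code{axes} (3 x 3 x n; columns of each
#'   slab are the sensitive axes x, y, z), \code{labels} (3n channel labels),
#'   \code{sensor_id}, \code{axis_tag}.
#' @export
build_helmet_array <- function(n_sensors = 30, scalp_radius = 0.09,
                               standoff = 0.0065,
                               coverage = list(center = c(0, 0, 1),
                                               half_angle = 1.1),
                               head = NULL) {
  stopifnot(n_sensors >= 1)
  if (is.null(head)) head <- head_model(c(0, 0, 0), scalp_radius)
  if (scalp_radius <= head$radius - 1e-12)
    stop("scalp_radius must not be smaller than the head-model radius")
  r_sens <- scalp_radius + standoff
  cap_axis <- .normalize(coverage$center)
  half_angle <- coverage$half_angle
  # placeable-site limit: one sensor footprint (23 mm square package) per site
  site_area <- 0.023^2
  cap_area <- 2 * pi * r_sens^2 * (1 - cos(half_angle))
  max_sites <- floor(cap_area / site_area)
  if (n_sensors > max_sites)
    stop(sprintf("n_sensors = %d exceeds the %d placeable sites on this cap",
                 n_sensors, max_sites))

  # Fibonacci lattice on the cap, in a frame with the cap axis along +z;
  # a single sensor sits at the cap pole
  i <- seq_len(n_sensors)
  cosu <- if (n_sensors == 1L) 1
          else 1 - (i - 0.5) / n_sensors * (1 - cos(half_angle))
  sinu <- sqrt(pmax(0, 1 - cosu^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  dirs <- cbind(sinu * cos(phi), sinu * sin(phi), cosu)
  # rotate cap frame so +z maps onto the cap axis
  if (sum(abs(cap_axis - c(0, 0, 1))) > 1e-14) {
    v <- pracma_cross(c(0, 0, 1), cap_axis)
    s <- sqrt(sum(v^2)); cth <- cap_axis[3]
    vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
    Rc <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
    dirs <- dirs %*% t(Rc)
  }
  positions <- sweep(dirs * r_sens, 2, head$center, `+`)
  axes <- array(0, dim = c(3, 3, n_sensors))
  for (k in seq_len(n_sensors)) {
    u <- dirs[k, ]
    tp <- .tangential_pair(u)
    axes[, , k] <- cbind(tp[, 1], tp[, 2], u)
  }
  sensor_array(positions, axes)
}

#' Construct a sensor array from positions and axis triads
#'
#' @param positions n x 3 matrix of sensor positions (meters).
#' @param axes 3 x 3 x n array; columns of slab k are the orthonormal
#'   sensitive axes (x, y, z) of sensor k.
#' @param sensor_names optional sensor identifiers.
#' @return A \code{sensor_array}.
#' @export
sensor_array <- function(positions, axes, sensor_names = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, all(dim(axes) == c(3, 3, n)))
  for (k in seq_len(n)) {
    A <- axes[, , k]
    if (max(abs(crossprod(A) - diag(3))) > 1e-10)
      stop(sprintf("axis triad of sensor %d is not orthonormal", k))
  }
  if (is.null(sensor_names)) sensor_names <- sprintf("S%02d", seq_len(n))
  tags <- c("x", "y", "z")
  labels <- as.vector(t(outer(sensor_names, tags, paste, sep = "-")))
  structure(list(positions = positions, axes = axes,
                 sensor_names = sensor_names,
                 sensor_id = rep(seq_len(n), each = 3L),
                 axis_tag = rep(tags, n),
                 labels = labels),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("sensor_array: %d triaxial sensors, %d channels\n",
              nrow(x$positions), n_channels(x)))
  r <- sqrt(rowSums(x$positions^2))
  cat(sprintf("  radius range %.1f-%.1f mm from origin\n",
              1000 * min(r), 1000 * max(r)))
  invisible(x)
}

#' Number of channels in a sensor array
#' @param array a \code{sensor_array}.
#' @return integer channel count (3 per sensor).
#' @export
n_channels <- function(array) 3L * nrow(array$positions)

#' Per-channel orientation unit vectors
#'
#' @param array a \code{sensor_array}.
#' @return (3n) x 3 matrix; row i is the sensitive-axis unit vector of
#'   channel i (channels ordered sensor-major, axes x, y, z).
#' @export
channel_orientations <- function(array) {
  n <- nrow(array$positions)
  out <- matrix(0, 3L * n, 3L)
  for (k in seq_len(n)) out[(3 * k - 2):(3 * k), ] <- t(array$axes[, , k])
  out
}

#' Per-channel positions
#' @param array a \code{sensor_array}.
#' @return (3n) x 3 matrix of channel (sensor) positions.
#' @export
channel_positions <- function(array) {
  array$positions[array$sensor_id, , drop = FALSE]
}

#' Apply a rigid-body transform to a sensor array
#'
#' Positions map as p -> R p + t and each axis triad as A -> R A. The input
#' array is unmodified.
#'
#' @param array a \code{sensor_array}.
#' @param pose a \code{rigid_transform}.
#' @return the transformed \code{sensor_array}.
#' @export
apply_motion <- function(array, pose) {
  if (!inherits(pose, "rigid_transform")) stop("pose must be a rigid_transform")
  R <- pose$rotation
  pos <- array$positions %*% t(R)
  pos <- sweep(pos, 2, pose$translation, `+`)
  dimnames(pos) <- dimnames(array$positions)
  axes <- array$axes
  for (k in seq_len(dim(axes)[3])) axes[, , k] <- R %*% axes[, , k]
  out <- array
  out$positions <- pos
  out$axes <- axes
  out
}

#' Motion trace at 120 Hz
#'
#' @param timestamps seconds, strictly increasing with uniform step 1/fs.
#' @param poses list of \code{rigid_transform}, one per timestamp.
#' @param fs sampling rate (Hz, default 120).
#' @return object of class \code{motion_trace}.
#' @export
motion_trace <- function(timestamps, poses, fs = 120) {
  stopifnot(length(timestamps) == length(poses))
  dt <- diff(timestamps)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-9))
    stop("timestamps must strictly increase with uniform step 1/fs")
  structure(list(timestamps = timestamps, poses = poses, fs = fs),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("motion_trace: %d poses at %g Hz (%.1f s)\n",
              length(x$poses), x$fs, length(x$poses) / x$fs))
  invisible(x)
}

#' Algebraic least-squares sphere fit
#'
#' Fits center c and radius r to points p by the linear system
#' |p|^2 = 2 c.p + (r^2 - |c|^2).
#'
#' @param points n x 3 matrix (n >= 4, non-coplanar).
#' @return a \code{head_model}.
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points to fit a sphere")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  qrA <- qr(A)
  if (qrA$rank < 4)
    stop("degenerate point set (coplanar or coincident): sphere not identifiable")
  x <- qr.coef(qrA, b)
  center <- x[1:3]
  r2 <- x[4] + sum(center^2)
  if (r2 <= 0) stop("degenerate point set: non-positive fitted radius")
  head_model(center, sqrt(r2))
}

#' Radial/tangential basis of each sensor relative to a sphere
#'
#' @param array a \code{sensor_array}.
#' @param head a \code{head_model}.
#' @return list with \code{radial} (n x 3 outward unit vectors) and
#'   \code{tangential} (3 x 2 x n orthonormal tangential pairs).
#' @export
radial_tangential_basis <- function(array, head) {
  rel <- sweep(array$positions, 2, head$center, `-`)
  d <- sqrt(rowSums(rel^2))
  if (any(d < 1e-9)) stop("sensor located at the sphere center")
  radial <- rel / d
  n <- nrow(rel)
  tang <- array(0, dim = c(3, 2, n))
  for (k in seq_len(n)) tang[, , k] <- .tangential_pair(radial[k, ])
  list(radial = radial, tangential = tang)
}

#' Tag each channel as radial or tangential
#'
#' The channel whose axis has the largest absolute projection on the outward
#' radial direction of its sensor is tagged radial; ties break in axis order
#' (x before y before z).
#'
#' @param array a \code{sensor_array}.
#' @param head a \code{head_model}.
#' @return logical vector over channels, TRUE for the radial channel of each
#'   sensor.
#' @export
radial_channel_mask <- function(array, head) {
  basis <- radial_tangential_basis(array, head)
  n <- nrow(array$positions)
  mask <- logical(3L * n)
  for (k in seq_len(n)) {
    dots <- abs(as.numeric(basis$radial[k, ] %*% array$axes[, , k]))
    mask[3L * (k - 1L) + which.max(dots)] <- TRUE
  }
  mask
}

#' Channel table of an array
#'
#' @param array a \code{sensor_array}.
#' @return data.frame with one row per channel: sensor id, axis tag, position
#'   (m) and orientation unit vector.
#' @export
channel_table <- function(array) {
  pos <- channel_positions(array)
  ori <- channel_orientations(array)
  data.frame(channel = array$labels,
             sensor = array$sensor_names[array$sensor_id],
             axis = array$axis_tag,
             px = pos[, 1], py = pos[, 2], pz = pos[, 3],
             ox = ori[, 1], oy = ori[, 2], oz = ori[, 3],
             stringsAsFactors = FALSE)
}

#' Serialize a channel table to JSON
#' @param array a \code{sensor_array}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_channel_table <- function(array, path) {
  jsonlite::write_json(channel_table(array), path, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
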