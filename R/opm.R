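# OPM sensor response model. SERF magnetometers have a Lorentzian zero-field
# resonance: a quasi-static field step dB away from the zero point reduces the
# effective gain by eps = x / (1 + x), x = (dB / Gamma)^2, where Gamma is the
# resonance half-width. White sensor noise is specified as an amplitude
# spectral density in fT/sqrt(Hz).

#' Lorentzian gain model
#' @param linewidth_nT resonance half-width Gamma in nT (> 0).
#' @return object of class \code{gain_model}.
#' @export
gain_model <- function(linewidth_nT) {
  stopifnot(linewidth_nT > 0)
  structure(list(linewidth_nT = linewidth_nT), class = "gain_model")
}

#' Fractional gain error for a quasi-static field step
#'
#' eps = x / (1 + x) with x = (dB / Gamma)^2; monotone increasing in the step
#' and bounded in [0, 1).
#'
#' @param step_nT field step dB in nT (>= 0; vectorized).
#' @param gm a \code{gain_model}.
#' @return gain error as a fraction in [0, 1).
#' @export
gain_error <- function(step_nT, gm) {
  if (any(step_nT < 0)) stop("field step must be non-negative")
  x <- (step_nT / gm$linewidth_nT)^2
  x / (1 + x)
}

#' Calibrate the resonance linewidth from one anchor point
#'
#' Inverts the Lorentzian gain-error model: Gamma = dB * sqrt((1 - eps)/eps).
#'
#' @param anchor_step_nT field step of the anchor (nT, > 0).
#' @param anchor_error gain error at the anchor, a fraction in (0, 1).
#' @return a \code{gain_model} whose \code{gain_error(anchor_step_nT)}
#'   reproduces \code{anchor_error}.
#' @export
calibrate_linewidth <- function(anchor_step_nT = 3, anchor_error = 0.038) {
  if (anchor_error <= 0 || anchor_error >= 1)
    stop("anchor_error must lie strictly in (0, 1)")
  stopifnot(anchor_step_nT > 0)
  gain_model(anchor_step_nT * sqrt((1 - anchor_error) / anchor_error))
}

#' Field step along a sensor axis after a head rotation
#'
#' A sensor zeroed at rest in a uniform field of magnitude B sees a field
#' change of B*sin(theta) along its sensitive axis after the head (and
#' sensor) rotates by theta.
#'
#' @param B_nT uniform-field magnitude, nT (>= 0).
#' @param theta_deg rotation angle, degrees.
#' @return field step in nT.
#' @export
rotation_field_step <- function(B_nT, theta_deg) {
  if (any(B_nT < 0)) stop("field magnitude must be non-negative")
  B_nT * sin(theta_deg * pi / 180)
}

#' White-noise model
#' @param density_fT amplitude spectral density, fT/sqrt(Hz) (>= 0).
#' @param seed integer seed.
#' @return object of class \code{noise_model}.
#' @export
noise_model <- function(density_fT = 15, seed = 1L) {
  stopifnot(density_fT >= 0)
  structure(list(density_fT = density_fT, seed = as.integer(seed)),
            class = "noise_model")
}

#' Per-sample noise standard deviation
#' @param nm a \code{noise_model}.
#' @param fs sampling rate, Hz.
#' @return standard deviation in tesla of white noise whose one-sided
#'   spectral density equals \code{nm$density_fT} up to the Nyquist rate.
#' @export
noise_sigma <- function(nm, fs) nm$density_fT * 1e-15 * sqrt(fs / 2)

#' Synthesize OPM channel data from true fields
#'
#' Applies the per-channel Lorentzian gain attenuation (1 - eps) implied by
#' each channel's quasi-static field step and adds seeded white noise of
#' standard deviation density * sqrt(fs / 2).
#'
#' @param true_fields channels x time matrix, tesla.
#' @param gm a \code{gain_model}, or NULL for an ideal (unit-gain) sensor.
#' @param nm a \code{noise_model}, or NULL for no noise.
#' @param fs sampling rate, Hz (> 0).
#' @param step_nT per-channel quasi-static field step (nT) used for the gain
#'   error; scalar or length-channels. Default 0 (no gain error).
#' @return channels x time matrix, tesla.
#' @export
synthesize_channels <- function(true_fields, gm = NULL, nm = NULL, fs,
                                step_nT = 0) {
  stopifnot(fs > 0)
  true_fields <- as.matrix(true_fields)
  nc <- nrow(true_fields)
  if (!(length(step_nT) %in% c(1L, nc)))
    stop("step_nT must be scalar or one value per channel")
  out <- true_fields
  if (!is.null(gm)) {
    eps <- gain_error(rep_len(step_nT, nc), gm)
    out <- out * (1 - eps)
  }
  if (!is.null(nm) && nm$density_fT > 0) {
    sigma <- noise_sigma(nm, fs)
    noise <- local_rng(nm$seed,
                       matrix(stats::rnorm(length(out), sd = sigma), nc))
    out <- out + noise
  }
  out
}
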