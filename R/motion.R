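#' Order parameter of a small-amplitude wobble
#'
#' Small-amplitude axially symmetric fluctuation of the C-H vector with
#' root-mean-square angle `theta_rms`:
#' `S = 1 - (3/2) <theta^2>` with theta in radians. Valid for small
#' amplitudes; angles above 30 degrees are outside the validity window and
#' trigger a warning. Results below 0 are floored at 0 with a warning.
#'
#' @param theta_rms root-mean-square fluctuation angle, degrees.
#' @return order parameter in [0, 1].
#' @export
wobble_S2 <- function(theta_rms) {
  if (any(theta_rms < 0)) stop_invalid("theta_rms must be non-negative")
  if (any(theta_rms > 30))
    warning("theta_rms above 30 degrees is outside the small-amplitude validity window")
  s <- 1 - 1.5 * deg2rad(theta_rms)^2
  if (any(s < 0)) {
    warning("wobble order parameter floored at 0")
    s <- pmax(s, 0)
  }
  s
}

#' Wobble angle from an order parameter
#'
#' Closed-form inverse of [wobble_S2()]: `theta = sqrt(2 (1 - S) / 3)`,
#' returned in degrees.
#'
#' @param S2 order parameter in (0, 1].
#' @return root-mean-square angle, degrees.
#' @export
wobble_angle <- function(S2) {
  if (any(S2 > 1)) stop_invalid("order parameter cannot exceed 1")
  if (any(S2 <= 0)) stop_invalid("order parameter must be positive for inversion")
  rad2deg(sqrt(2 * (1 - S2) / 3))
}

#' N-site jump model
#'
#' Discrete jumps of the C-H vector between `N` orientations with
#' equilibrium populations `p_i` and pairwise inter-orientation angles
#' `theta_ij`.
#'
#' @param populations fractions summing to 1.
#' @param angles `N x N` symmetric matrix of angles, degrees, zero
#'   diagonal. For `N = 2` a single scalar angle is accepted.
#' @return object of class `jump_model`.
#' @export
jump_model <- function(populations, angles) {
  p <- as.numeric(populations)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop_invalid("populations must be non-negative and sum to 1")
  n <- length(p)
  if (is.null(dim(angles))) {
    if (n == 2 && length(angles) == 1) {
      angles <- matrix(c(0, angles, angles, 0), 2, 2)
    } else stop_invalid("angles must be an N x N matrix")
  }
  angles <- as.matrix(angles)
  if (!all(dim(angles) == n)) stop_invalid("angle matrix must be %d x %d", n, n)
  if (any(abs(diag(angles)) > 1e-10)) stop_invalid("angle matrix diagonal must be zero")
  if (any(abs(angles - t(angles)) > 1e-8)) stop_invalid("angle matrix must be symmetric")
  structure(list(populations = p, angles = angles), class = "jump_model")
}

#' Order parameter of an N-site jump model
#'
#' `S = sum_ij p_i p_j P2(cos theta_ij)` with the second Legendre
#' polynomial `P2(x) = (3 x^2 - 1) / 2`. Equals 1 only when all occupied
#' orientations coincide; bounded below by -1/2.
#'
#' @param model a [jump_model()].
#' @return order parameter in [-0.5, 1].
#' @export
jump_S2 <- function(model) {
  stopifnot(inherits(model, "jump_model"))
  p <- model$populations
  P2 <- (3 * cos(deg2rad(model$angles))^2 - 1) / 2
  as.numeric(t(p) %*% P2 %*% p)
}

#' Order parameter of fast uniaxial rotation
#'
#' Unrestricted fast rotation of the C-H vector about an axis inclined at
#' `beta` degrees averages the dipolar coupling by `P2(cos beta)`. The
#' signed value is returned; Pake splittings are sign-blind, so use the
#' absolute value to predict observable couplings.
#'
#' @param beta angle between the C-H vector and the rotation axis,
#'   degrees, in [0, 90].
#' @return `P2(cos beta)`, in [-0.5, 1].
#' @export
uniaxial_S <- function(beta) {
  if (any(beta < 0 | beta > 90)) stop_invalid("beta must lie in [0, 90] degrees")
  (3 * cos(deg2rad(beta))^2 - 1) / 2
}

#' Classify a motion as averaging dipolar couplings or not
#'
#' Motions faster than the inverse dipolar linewidth average the one-bond
#' C-H coupling; the default threshold is 40 microseconds (strict
#' inequality: exactly at threshold counts as static).
#'
#' @param tau_c correlation time, s, positive.
#' @param threshold averaging threshold, s.
#' @return `"averaged"` or `"static"` per element.
#' @export
classify_averaging <- function(tau_c, threshold = 4e-5) {
  if (any(tau_c <= 0)) stop_invalid("tau_c must be positive")
  ifelse(tau_c < threshold, "averaged", "static")
}
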