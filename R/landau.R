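#' Two-component order parameter from Euler angles
#'
#' The conformation of the double helix is encoded in a normalised
#' two-component complex order parameter obtained by an Euler rotation of
#' the reference state (1, 0):
#' `Psi = (cos(theta/2) exp(-i(phi+chi)/2), sin(theta/2) exp(i(phi-chi)/2))`.
#' The first component tracks the superhelical (axis) conformation, the
#' second the internal base-pair winding.
#'
#' @param phi,theta,chi Euler angles, radians. Vectorised.
#' @return A complex matrix with columns `c1` and `c2`, one row per angle
#'   triple; unit norm row-wise.
#' @export
#' @examples
#' order_parameter(0.3, 1.2, -0.5)
order_parameter <- function(phi, theta, chi) {
  stopifnot(is.numeric(phi), is.numeric(theta), is.numeric(chi))
  n <- max(length(phi), length(theta), length(chi))
  phi <- rep_len(phi, n); theta <- rep_len(theta, n); chi <- rep_len(chi, n)
  c1 <- cos(theta / 2) * exp(-1i * (phi + chi) / 2)
  c2 <- sin(theta / 2) * exp(1i * (phi - chi) / 2)
  cbind(c1 = c1, c2 = c2)
}

#' Euler rotation matrix acting on the order parameter
#'
#' The SU(2) rotation whose first column applied to the reference state
#' (1, 0) reproduces [order_parameter()].
#'
#' @param phi,theta,chi Euler angles, radians (scalars).
#' @return A 2x2 complex matrix.
#' @export
euler_rotation <- function(phi, theta, chi) {
  check_scalar_number(phi, "phi"); check_scalar_number(theta, "theta")
  check_scalar_number(chi, "chi")
  ct <- cos(theta / 2); st <- sin(theta / 2)
  matrix(
    c(ct * exp(-1i * (phi + chi) / 2),  st * exp(1i * (phi - chi) / 2),
      -st * exp(-1i * (phi - chi) / 2), ct * exp(1i * (phi + chi) / 2)),
    nrow = 2
  )
}

#' Discretised Euler-angle path along the DNA helix axis
#'
#' A sampled path s -> (phi(s), theta(s), chi(s)) in reduced arc-length
#' units. Derivative columns may be supplied; any missing ones are filled
#' by central finite differences (one-sided at the ends). `theta` must
#' stay inside the open interval (0, pi) (tolerance 1e-9 at the
#' endpoints): the poles are coordinate singularities of the Euler
#' parametrisation.
#'
#' @param s Strictly increasing arc-length grid, length >= 2.
#' @param phi,theta,chi Euler angles at each sample, radians.
#' @param dphi,dtheta,dchi Optional derivative samples d/ds.
#' @return A tibble of class `euler_path` with columns
#'   `s, phi, theta, chi, dphi, dtheta, dchi`.
#' @export
#' @examples
#' s <- seq(0, 1, length.out = 101)
#' euler_path(s, phi = 2 * pi * s, theta = rep(pi / 4, 101), chi = 15 * s)
euler_path <- function(s, phi, theta, chi,
                       dphi = NULL, dtheta = NULL, dchi = NULL) {
  stopifnot(is.numeric(s), is.numeric(phi), is.numeric(theta), is.numeric(chi))
  n <- length(s)
  if (n < 2) stop_invalid("an euler_path needs at least 2 samples")
  if (any(diff(s) <= 0)) stop_invalid("`s` must be strictly increasing")
  if (length(phi) != n || length(theta) != n || length(chi) != n) {
    stop_invalid("`phi`, `theta`, `chi` must have the same length as `s`")
  }
  # open interval with a 1e-9 guard band: the poles are parametrisation
  # singularities, handled only by the closed-form limit helpers
  if (any(theta <= 1e-9) || any(theta >= pi - 1e-9)) {
    stop_invalid("`theta` must lie strictly inside (0, pi)")
  }
  if (is.null(dphi)) dphi <- finite_diff(phi, s)
  if (is.null(dtheta)) dtheta <- finite_diff(theta, s)
  if (is.null(dchi)) dchi <- finite_diff(chi, s)
  for (nm in c("dphi", "dtheta", "dchi")) {
    if (length(get(nm)) != n) stop_invalid("`%s` must have length %d", nm, n)
  }
  out <- tibble::tibble(
    s = s, phi = phi, theta = theta, chi = chi,
    dphi = dphi, dtheta = dtheta, dchi = dchi
  )
  class(out) <- c("euler_path", class(out))
  out
}

# central differences inside, one-sided at the ends; non-uniform grids ok
finite_diff <- function(y, x) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

#' Landau free-energy density in Euler angles
#'
#' The elastic free energy per unit arc length of the double helix,
#' obtained by substituting the Euler-angle order parameter into the
#' quadratic Landau expansion:
#' \deqn{F = \frac{B}{2}\left[\left(\frac{d\theta}{ds}\right)^2 +
#'   \left(\frac{d\phi}{ds}\right)^2 \sin^2\theta\right] +
#'   \frac{C}{2}\left[\frac{d\phi}{ds}\cos\theta +
#'   \frac{d\chi}{ds}\right]^2}
#' The first bracket is the squared curvature of the helix axis, the
#' second the squared torsion. The result is non-negative for positive
#' rigidities.
#'
#' @param theta Euler angle theta, radians. Vectorised with the
#'   derivatives.
#' @param dtheta,dphi,dchi Derivatives of the Euler angles with respect to
#'   arc length.
#' @param constants An [elastic_constants()] object.
#' @param units `"reduced"` (kB T per unit arc length; default) or `"si"`
#'   (J per nm, using the SI rigidities).
#' @return Free-energy density, same length as the inputs.
#' @export
#' @examples
#' # a straight rod twisted at rate t has density (C/2) t^2
#' landau_free_energy_density(theta = 0, dtheta = 0, dphi = 0, dchi = 2)
landau_free_energy_density <- function(theta, dtheta, dphi, dchi,
                                       constants = elastic_constants(),
                                       units = c("reduced", "si")) {
  stopifnot(inherits(constants, "elastic_constants"))
  units <- match.arg(units)
  B <- if (units == "reduced") constants$B_red else constants$B_si
  C <- if (units == "reduced") constants$C_red else constants$C_si
  (B / 2) * (dtheta^2 + dphi^2 * sin(theta)^2) +
    (C / 2) * (dphi * cos(theta) + dchi)^2
}

#' Torsion of the helix from Euler-angle rates
#'
#' The torsion per unit arc length, `tau = dphi/ds * cos(theta) + dchi/ds`.
#' Integrating `tau / (2 pi)` along the molecule gives the twist.
#'
#' @param dphi,dchi Euler-angle derivatives with respect to arc length.
#' @param theta Euler angle theta, radians.
#' @return Torsion, same length as the inputs.
#' @export
#' @examples
#' torsion(dphi = 0.5, theta = pi / 2, dchi = 1) # 1: cos(pi/2) kills dphi
torsion <- function(dphi, theta, dchi) {
  dphi * cos(theta) + dchi
}

#' Twist of a discretised Euler path
#'
#' The twist `Tw = (1 / 2 pi) * integral of tau ds` evaluated by
#' trapezoidal quadrature on the path's own grid (no resampling), with
#' `tau` the [torsion()] at each sample.
#'
#' @param path An [euler_path()].
#' @return The twist (dimensionless).
#' @export
#' @examples
#' s <- seq(0, 1, length.out = 201)
#' p <- euler_path(s, phi = rep(0, 201), theta = rep(pi / 2, 201),
#'                 chi = 2 * pi * 15.75 * s)
#' twist_number(p) # 15.75
twist_number <- function(path) {
  if (!inherits(path, "euler_path")) {
    stop_invalid("`path` must be an euler_path")
  }
  if (nrow(path) < 2) stop_invalid("an euler_path needs at least 2 samples")
  tau <- torsion(path$dphi, path$theta, path$dchi)
  trapezoid(path$s, tau) / (2 * pi)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)])) / 2
}
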