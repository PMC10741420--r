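#' Parameters of the chiral-gauge effective potential
#'
#' The torque-driven B-Z transition of double-stranded DNA is described by
#' a tilted double-well potential in the chiral gauge variable `rho`, the
#' rotational angle between successive base pairs (rad/bp; `rho > 0` for a
#' right-handed, `rho < 0` for a left-handed helix):
#' \deqn{V_{eff}(\rho) = V_0\left[\left(\frac{\rho}{\omega_0}\right)^2 -
#'   1\right]^2 - (\tau - \tau_c)\,\rho.}
#' At `tau = tau_c` the potential is an even double well with minima at
#' `rho = +/- omega0`; a torque above (below) the critical value tilts the
#' well toward the right-handed (left-handed) helix.
#'
#' @param tau Applied torque, J (default: the critical torque, giving the
#'   symmetric well).
#' @param v0 Well-depth scale, J (default 6e-21).
#' @param omega0 Equilibrium helix rotation per bp, rad/bp (default
#'   `2 pi / 10.5`).
#' @param tau_c Critical torque, J (default -7.9e-21).
#' @return An object of class `effective_potential`.
#' @export
#' @examples
#' effective_potential(tau = -5e-21)
effective_potential <- function(tau = -7.9e-21, v0 = 6e-21,
                                omega0 = 2 * pi / 10.5, tau_c = -7.9e-21) {
  check_scalar_number(tau, "tau")
  check_scalar_number(v0, "v0", positive = TRUE)
  check_scalar_number(omega0, "omega0")
  if (omega0 == 0) stop_invalid("`omega0` must be non-zero")
  check_scalar_number(tau_c, "tau_c")
  structure(
    list(v0 = v0, omega0 = omega0, tau = tau, tau_c = tau_c),
    class = "effective_potential"
  )
}

#' @export
print.effective_potential <- function(x, ...) {
  cat(sprintf("<effective_potential> V0 = %.3g J, omega0 = %.4g rad/bp, tau - tau_c = %.3g J\n",
              x$v0, x$omega0, x$tau - x$tau_c))
  invisible(x)
}

#' Evaluate the effective potential
#'
#' @param rho Chiral gauge variable, rad/bp. Vectorised.
#' @param params An [effective_potential()] object.
#' @return Energy in joules, same length as `rho`.
#' @export
#' @examples
#' p <- effective_potential()
#' veff(c(-p$omega0, 0, p$omega0), p) # 0, V0, 0 at the critical torque
veff <- function(rho, params = effective_potential()) {
  stopifnot(inherits(params, "effective_potential"), is.numeric(rho))
  params$v0 * ((rho / params$omega0)^2 - 1)^2 -
    (params$tau - params$tau_c) * rho
}

#' Stationary points of the effective potential
#'
#' Roots of `dVeff/drho = 0`, a depressed cubic
#' `rho^3 - omega0^2 rho = (tau - tau_c) omega0^4 / (4 V0)`,
#' solved in closed form: the trigonometric method when all three roots
#' are real, Cardano's formula otherwise. Each root is classified by the
#' sign of the second derivative. At the critical torque the roots are
#' exactly `-omega0, 0, +omega0` (maximum at 0, minima at the wells).
#'
#' @param params An [effective_potential()] object.
#' @return A tibble with columns `rho` (ascending), `type`
#'   (`"min"`/`"max"`/`"inflection"`) and `veff`.
#' @export
#' @examples
#' veff_stationary_points(effective_potential())
veff_stationary_points <- function(params = effective_potential()) {
  stopifnot(inherits(params, "effective_potential"))
  w0 <- params$omega0
  # depressed cubic t^3 + a t + b = 0
  a <- -w0^2
  b <- -(params$tau - params$tau_c) * w0^4 / (4 * params$v0)
  roots <- solve_depressed_cubic(a, b)
  roots <- sort(roots)
  d2 <- (4 * params$v0 / w0^2) * (3 * (roots / w0)^2 - 1)
  type <- ifelse(abs(d2) < 1e-12 * (4 * params$v0 / w0^2), "inflection",
                 ifelse(d2 > 0, "min", "max"))
  tibble::tibble(rho = roots, type = type, veff = veff(roots, params))
}

# real roots of t^3 + a t + b = 0 (closed form)
solve_depressed_cubic <- function(a, b) {
  if (b == 0) {
    # t (t^2 + a) = 0 exactly
    if (a < 0) return(c(-sqrt(-a), 0, sqrt(-a)))
    return(0)
  }
  disc <- -4 * a^3 - 27 * b^2
  if (disc > 0) {
    # three distinct real roots: trigonometric method (a < 0 here)
    r <- 2 * sqrt(-a / 3)
    arg <- (3 * b) / (a * r)
    arg <- min(1, max(-1, arg)) # clamp rounding noise
    phi <- acos(arg)
    k <- 0:2
    r * cos(phi / 3 - 2 * pi * k / 3)
  } else if (disc == 0) {
    # repeated root
    t1 <- 3 * b / a
    t2 <- -3 * b / (2 * a)
    unique(c(t1, t2))
  } else {
    # one real root: Cardano
    d <- sqrt(b^2 / 4 + a^3 / 27)
    cbrt(-b / 2 + d) + cbrt(-b / 2 - d)
  }
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Global minimum of the effective potential
#'
#' The stationary point of type `"min"` with the lowest energy; its sign
#' tells which handedness the applied torque favours.
#'
#' @param params An [effective_potential()] object.
#' @return A one-row tibble (`rho`, `type`, `veff`).
#' @export
#' @examples
#' veff_global_minimum(effective_potential(tau = -5e-21)) # rho > 0
veff_global_minimum <- function(params = effective_potential()) {
  st <- veff_stationary_points(params)
  minima <- st[st$type == "min", , drop = FALSE]
  if (nrow(minima) == 0) stop_invalid("no local minimum found")
  minima[which.min(minima$veff), , drop = FALSE]
}

#' Sampled profile of the effective potential
#'
#' @param params An [effective_potential()] object.
#' @param rho_min,rho_max Scan range, rad/bp (default +/- 2 omega0).
#' @param step Grid spacing, rad/bp.
#' @return A tibble of class `veff_profile` with columns `rho`, `veff`.
#' @export
#' @examples
#' head(veff_profile(effective_potential()))
veff_profile <- function(params = effective_potential(),
                         rho_min = -2 * abs(params$omega0),
                         rho_max = 2 * abs(params$omega0),
                         step = abs(params$omega0) / 50) {
  stopifnot(inherits(params, "effective_potential"))
  check_scalar_number(step, "step", positive = TRUE)
  if (rho_min >= rho_max) stop_invalid("`rho_min` must be below `rho_max`")
  rho <- seq(rho_min, rho_max, by = step)
  out <- tibble::tibble(rho = rho, veff = veff(rho, params))
  class(out) <- c("veff_profile", class(out))
  attr(out, "params") <- params
  out
}
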