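#' Torus-knot (Hopfion) configuration
#'
#' A closed twisted string on a torus is characterised by its toroidal
#' winding `p`, poloidal winding `q` and Hopf charge `w = p * q`, which for
#' closed circular DNA equals the linking number. `r_deg` is the bending
#' angle of the helix axis after the torus mapping (half the Euler angle
#' theta, so it lives in the open interval (0, 90) degrees); `m` and `n`
#' are the constant rates of the toroidal and poloidal coordinates with
#' arc length.
#'
#' Profiles scan non-integer `p` with `q = w / p` held continuous;
#' [integer_minimum()] restricts to integer factorizations.
#'
#' @param w Hopf charge (> 0); the linking number in canonical use.
#' @param p Toroidal winding number (> 0).
#' @param q Poloidal winding number; defaults to `w / p`.
#' @param r_deg Bending angle R in degrees, open interval (0, 90).
#' @param m,n Rates of the toroidal / poloidal angles per unit arc length
#'   (default 1).
#' @return An object of class `hopfion_config`.
#' @export
#' @examples
#' hopfion_config(w = 14, p = 2, r_deg = 20)
hopfion_config <- function(w, p, q = w / p, r_deg, m = 1, n = 1) {
  check_scalar_number(w, "w", positive = TRUE)
  check_scalar_number(p, "p", positive = TRUE)
  check_scalar_number(q, "q", positive = TRUE)
  check_r_deg(r_deg)
  check_scalar_number(m, "m")
  check_scalar_number(n, "n")
  if (abs(p * q - w) > 1e-9) {
    stop_invalid("`p * q` must equal `w` (got %.12g != %.12g)", p * q, w)
  }
  structure(
    list(w = w, p = p, q = q, r_deg = r_deg, m = m, n = n),
    class = "hopfion_config"
  )
}

check_r_deg <- function(r_deg) {
  check_scalar_number(r_deg, "r_deg")
  if (r_deg <= 0 || r_deg >= 90) {
    stop_invalid("`r_deg` must lie in the open interval (0, 90), got %g", r_deg)
  }
  invisible(r_deg)
}

#' @export
print.hopfion_config <- function(x, ...) {
  cat(sprintf("<hopfion_config> W = %g = P x Q = %g x %g, R = %g deg, m = %g, n = %g\n",
              x$w, x$p, x$q, x$r_deg, x$m, x$n))
  invisible(x)
}

#' Map torus coordinates to Euler angles
#'
#' The torus-knot reduction fixes the Euler angles as linear functions of
#' the toroidal angle `phi_coord` and poloidal angle `theta_coord`:
#' `theta = 2 R`, `phi = P phi_coord + Q theta_coord`,
#' `chi = P phi_coord - Q theta_coord`. With constant coordinate rates
#' `d(phi_coord)/ds = m`, `d(theta_coord)/ds = n` and `dR/ds = 0` the
#' pushed-forward Euler rates are `dphi = P m + Q n`, `dchi = P m - Q n`,
#' `dtheta = 0` (see [map_angle_rates()]).
#'
#' @param r_rad Bending angle R in radians, open interval (0, pi/2).
#' @param p,q Toroidal and poloidal winding numbers.
#' @param phi_coord,theta_coord Toroidal and poloidal angles, radians.
#'   Vectorised.
#' @return A list with components `theta`, `phi`, `chi` (radians).
#' @export
#' @examples
#' map_angles(pi / 9, p = 2, q = 7, phi_coord = 0.1, theta_coord = 0.2)
map_angles <- function(r_rad, p, q, phi_coord = 0, theta_coord = 0) {
  check_scalar_number(r_rad, "r_rad")
  if (r_rad <= 0 || r_rad >= pi / 2) {
    stop_invalid("`r_rad` must lie in the open interval (0, pi/2), got %g", r_rad)
  }
  list(
    theta = rep_len(2 * r_rad, max(length(phi_coord), length(theta_coord))),
    phi = p * phi_coord + q * theta_coord,
    chi = p * phi_coord - q * theta_coord
  )
}

#' Euler-angle rates of a torus-knot configuration
#'
#' Derivatives with respect to arc length of the mapped Euler angles under
#' constant coordinate rates `m`, `n` and a fixed bending angle
#' (`dR/ds = 0`).
#'
#' @param p,q Winding numbers.
#' @param m,n Coordinate rates per unit arc length.
#' @return A list with components `dtheta` (0), `dphi` (`P m + Q n`) and
#'   `dchi` (`P m - Q n`).
#' @export
map_angle_rates <- function(p, q, m = 1, n = 1) {
  list(dtheta = 0, dphi = p * m + q * n, dchi = p * m - q * n)
}

#' Closed-form Hopfion free-energy density
#'
#' The Landau free-energy density evaluated on a torus-knot configuration
#' reduces to the closed form
#' \deqn{F(P) = \frac{B}{2}\left(Pm + \frac{W}{P}n\right)^2 \sin^2(2R) +
#'   2C\left(Pm\cos^2 R - \frac{W}{P}n\sin^2 R\right)^2,}
#' in kB T per unit arc length for reduced rigidities. The minus sign in
#' the torsion factor is fixed by the cross term of the Euler-angle
#' expansion (the `-2PQ (dphi/ds)(dTheta/ds) sin^2(2R)` contribution) and
#' is required for the density to agree with
#' [landau_free_energy_density()] composed with [map_angle_rates()] —
#' an identity the test-suite checks on random configurations.
#'
#' `p` is interpreted as the magnitude of the toroidal wrap number (the
#' writhe enters energy expressions through its absolute value).
#'
#' @param p Toroidal winding (> 0). Vectorised. May also be a
#'   [hopfion_config()], in which case the remaining arguments except
#'   `constants` and `units` are taken from it.
#' @param w Hopf charge (= linking number).
#' @param r_deg Bending angle in degrees, open interval (0, 90).
#' @param m,n Coordinate rates (default 1).
#' @param constants An [elastic_constants()] object.
#' @param units `"reduced"` (default) or `"si"`.
#' @return Free-energy density per unit arc length, same length as `p`.
#' @export
#' @examples
#' hopfion_free_energy(2.1, w = 14, r_deg = 22) # ~1071 kBT per unit length
#' hopfion_free_energy(hopfion_config(14, 2, r_deg = 20))
hopfion_free_energy <- function(p, w = NULL, r_deg = NULL, m = 1, n = 1,
                                constants = elastic_constants(),
                                units = c("reduced", "si")) {
  units <- match.arg(units)
  if (inherits(p, "hopfion_config")) {
    cfg <- p
    return(hopfion_free_energy(cfg$p, cfg$w, cfg$r_deg, cfg$m, cfg$n,
                               constants = constants, units = units))
  }
  stopifnot(inherits(constants, "elastic_constants"))
  if (!is.numeric(p) || length(p) < 1 || any(!is.finite(p))) {
    stop_invalid("`p` must be finite and numeric")
  }
  if (any(p <= 0)) stop_invalid("`p` must be strictly positive")
  check_scalar_number(w, "w", positive = TRUE)
  check_r_deg(r_deg)
  B <- if (units == "reduced") constants$B_red else constants$B_si
  C <- if (units == "reduced") constants$C_red else constants$C_si
  R <- deg2rad(r_deg)
  q <- w / p
  (B / 2) * (p * m + q * n)^2 * sin(2 * R)^2 +
    2 * C * (p * m * cos(R)^2 - q * n * sin(R)^2)^2
}

#' Total free energy of a DNA segment
#'
#' With a fixed bending angle and constant coordinate rates the Hopfion
#' density is independent of arc length, so the total energy over a
#' molecule of reduced length `b` is simply `E = F * b`.
#'
#' @param f Free-energy density (kB T per unit arc length).
#' @param b Arc length in reduced units (>= 0).
#' @return Total energy, kB T.
#' @export
#' @examples
#' total_energy(1071, 1)
total_energy <- function(f, b) {
  stopifnot(is.numeric(f), is.numeric(b))
  if (any(b < 0)) stop_invalid("`b` must be non-negative")
  f * b
}

#' Free-energy profile over the toroidal winding number
#'
#' Scans the closed-form Hopfion free energy over a grid of `p` values
#' with `q = w / p` continuous, then refines the best grid point by
#' bounded scalar minimisation (golden-section / parabolic interpolation,
#' tolerance 1e-8 in `p`). Both the grid minimum and the refined minimum
#' are reported.
#'
#' @param w Hopf charge (= linking number).
#' @param r_deg Bending angle, degrees, open interval (0, 90).
#' @param m,n Coordinate rates (default 1).
#' @param constants An [elastic_constants()] object.
#' @param p_start,p_stop Scan interval (0 < p_start < p_stop); `p_stop`
#'   defaults to `w`.
#' @param p_step Grid spacing (default 0.1, the resolution at which the
#'   canonical nucleosome minima are quoted).
#' @return An object of class `energy_profile`: a list with `grid` (tibble
#'   of `p`, `f`), `p_min_grid`, `f_min_grid`, `p_min`, `f_min` (refined)
#'   and `params`.
#' @export
#' @examples
#' pr <- energy_profile(w = 14, r_deg = 22)
#' glance(pr)
energy_profile <- function(w, r_deg, m = 1, n = 1,
                           constants = elastic_constants(),
                           p_start = 0.5, p_stop = w, p_step = 0.1) {
  check_scalar_number(w, "w", positive = TRUE)
  check_r_deg(r_deg)
  check_scalar_number(p_start, "p_start", positive = TRUE)
  check_scalar_number(p_stop, "p_stop", positive = TRUE)
  check_scalar_number(p_step, "p_step", positive = TRUE)
  if (p_start >= p_stop) stop_invalid("`p_start` must be below `p_stop`")
  p_grid <- seq(p_start, p_stop, by = p_step)
  if (length(p_grid) < 1) stop_invalid("empty scan grid")
  f_grid <- hopfion_free_energy(p_grid, w, r_deg, m, n, constants)
  i <- which.min(f_grid)
  # bracket the refined search by the neighbouring grid points
  lo <- if (i > 1) p_grid[i - 1] else p_grid[1]
  hi <- if (i < length(p_grid)) p_grid[i + 1] else p_grid[length(p_grid)]
  if (lo < hi) {
    opt <- stats::optimize(
      function(p) hopfion_free_energy(p, w, r_deg, m, n, constants),
      interval = c(lo, hi), tol = 1e-8
    )
    p_min <- opt$minimum
    f_min <- opt$objective
  } else {
    p_min <- p_grid[i]
    f_min <- f_grid[i]
  }
  if (f_grid[i] < f_min) { # refinement can never do worse than the grid
    p_min <- p_grid[i]
    f_min <- f_grid[i]
  }
  structure(
    list(
      grid = tibble::tibble(p = p_grid, f = f_grid),
      p_min_grid = p_grid[i],
      f_min_grid = f_grid[i],
      p_min = p_min,
      f_min = f_min,
      params = list(w = w, r_deg = r_deg, m = m, n = n,
                    B_red = constants$B_red, C_red = constants$C_red,
                    p_start = p_start, p_stop = p_stop, p_step = p_step)
    ),
    class = "energy_profile"
  )
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf(
    paste0("<energy_profile> W = %g, R = %g deg, m = %g, n = %g (%d grid points)\n",
           "  grid minimum    %.6g kBT/unit at P = %g\n",
           "  refined minimum %.6g kBT/unit at P = %.6g\n"),
    x$params$w, x$params$r_deg, x$params$m, x$params$n, nrow(x$grid),
    x$f_min_grid, x$p_min_grid, x$f_min, x$p_min
  ))
  invisible(x)
}

#' @rdname energy_profile
#' @param x An `energy_profile`.
#' @param ... Unused.
#' @method tidy energy_profile
#' @export
tidy.energy_profile <- function(x, ...) {
  x$grid
}

#' @rdname energy_profile
#' @method glance energy_profile
#' @export
glance.energy_profile <- function(x, ...) {
  tibble::tibble(
    w = x$params$w, r_deg = x$params$r_deg, m = x$params$m, n = x$params$n,
    p_min_grid = x$p_min_grid, f_min_grid = x$f_min_grid,
    p_min = x$p_min, f_min = x$f_min,
    n_grid = nrow(x$grid)
  )
}

#' Integer-factorization free-energy minimum
#'
#' The physically admissible torus knots have integer winding numbers with
#' `P * Q = W`. This evaluates the closed-form free energy at every such
#' factorization and returns the minimiser (ties broken toward smaller
#' `P`).
#'
#' @param w Positive integer Hopf charge.
#' @param r_deg Bending angle, degrees.
#' @param m,n Coordinate rates (default 1).
#' @param constants An [elastic_constants()] object.
#' @return An object of class `integer_minimum`: a list with `candidates`
#'   (tibble of `p`, `q`, `f`), `p_best`, `f_best` and `params`.
#' @export
#' @examples
#' integer_minimum(14, r_deg = 20) # P = 2 among {1, 2, 7, 14}
integer_minimum <- function(w, r_deg, m = 1, n = 1,
                            constants = elastic_constants()) {
  pairs <- hopf_factorizations(w)
  f <- hopfion_free_energy(pairs$p, w, r_deg, m, n, constants)
  candidates <- tibble::tibble(p = pairs$p, q = pairs$q, f = f)
  i <- which.min(candidates$f) # candidates sorted by p, so first min wins ties
  structure(
    list(
      candidates = candidates,
      p_best = candidates$p[i],
      f_best = candidates$f[i],
      params = list(w = w, r_deg = r_deg, m = m, n = n,
                    B_red = constants$B_red, C_red = constants$C_red)
    ),
    class = "integer_minimum"
  )
}

#' @export
print.integer_minimum <- function(x, ...) {
  cat(sprintf("<integer_minimum> W = %g, R = %g deg: best P = %d, F = %.6g kBT/unit\n",
              x$params$w, x$params$r_deg, x$p_best, x$f_best))
  invisible(x)
}

#' @rdname integer_minimum
#' @param x An `integer_minimum`.
#' @param ... Unused.
#' @method tidy integer_minimum
#' @export
tidy.integer_minimum <- function(x, ...) {
  x$candidates
}

#' @rdname integer_minimum
#' @method glance integer_minimum
#' @export
glance.integer_minimum <- function(x, ...) {
  tibble::tibble(
    w = x$params$w, r_deg = x$params$r_deg, m = x$params$m, n = x$params$n,
    p_best = x$p_best, f_best = x$f_best,
    n_candidates = nrow(x$candidates)
  )
}
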