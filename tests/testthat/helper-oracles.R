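# Independent oracles used across the test files. These deliberately avoid
# the package's own closed-form code paths.

# Euler (SU(2)) rotation applied to the reference state (1, 0): an explicit
# complex 2x2 matrix multiply, written out from the rotation's definition.
oracle_rotated_reference <- function(phi, theta, chi) {
  m <- matrix(
    c(cos(theta / 2) * exp(-1i * (phi + chi) / 2),
      sin(theta / 2) * exp(1i * (phi - chi) / 2),
      -sin(theta / 2) * exp(-1i * (phi - chi) / 2),
      cos(theta / 2) * exp(1i * (phi + chi) / 2)),
    nrow = 2
  )
  as.vector(m %*% c(1 + 0i, 0 + 0i))
}

# Free energy of a torus-knot configuration computed the long way round:
# push the coordinate rates through the angle mapping and evaluate the
# general Euler-angle density term by term.
oracle_energy_via_euler <- function(p, w, r_deg, m, n, B = 50, C = 95) {
  q <- w / p
  theta <- 2 * r_deg * pi / 180
  dphi <- p * m + q * n
  dchi <- p * m - q * n
  (B / 2) * (0^2 + dphi^2 * sin(theta)^2) +
    (C / 2) * (dphi * cos(theta) + dchi)^2
}

# Brute-force divisor count.
oracle_divisor_count <- function(w) sum(w %% seq_len(w) == 0)

# Stationary points of the tilted quartic by dense scan + bisection on the
# numerically differentiated potential.
oracle_veff_stationary <- function(params, half_width = 3) {
  w0 <- abs(params$omega0)
  v <- function(rho) {
    params$v0 * ((rho / params$omega0)^2 - 1)^2 -
      (params$tau - params$tau_c) * rho
  }
  h <- w0 * 1e-7
  dv <- function(rho) (v(rho + h) - v(rho - h)) / (2 * h)
  grid <- seq(-half_width * w0, half_width * w0, length.out = 20001)
  s <- dv(grid)
  roots <- c()
  for (i in seq_len(length(grid) - 1)) {
    if (s[i] == 0) roots <- c(roots, grid[i])
    else if (s[i] * s[i + 1] < 0) {
      roots <- c(roots, uniroot(dv, c(grid[i], grid[i + 1]),
                                tol = 1e-14)$root)
    }
  }
  sort(unique(roots))
}
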