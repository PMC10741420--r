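test_that("order parameter has unit norm and matches the rotation oracle", {
  set.seed(101)
  for (i in 1:200) {
    phi <- runif(1, -2 * pi, 2 * pi)
    theta <- runif(1, 1e-3, pi - 1e-3)
    chi <- runif(1, -2 * pi, 2 * pi)
    psi <- order_parameter(phi, theta, chi)
    expect_lt(abs(sum(Mod(psi)^2) - 1), 1e-12)
    expect_lt(max(Mod(psi[1, ] - oracle_rotated_reference(phi, theta, chi))),
              1e-12)
  }
  # theta = 0 pole: all weight on the first component
  psi0 <- order_parameter(0.7, 0, -0.3)
  expect_equal(psi0[1, "c2"], 0 + 0i, ignore_attr = TRUE)
  expect_equal(psi0[1, "c1"], exp(-1i * (0.7 - 0.3) / 2), ignore_attr = TRUE)
})

test_that("package rotation matrix is unitary and reproduces the order parameter", {
  set.seed(77)
  for (i in 1:50) {
    ang <- runif(3, -pi, pi)
    U <- euler_rotation(ang[1], ang[2], ang[3])
    expect_lt(max(Mod(Conj(t(U)) %*% U - diag(2))), 1e-12)
    expect_lt(max(Mod(U %*% c(1, 0) -
                        as.vector(order_parameter(ang[1], ang[2], ang[3])))),
              1e-12)
  }
})

test_that("Euler density reduces to pure twist and pure bend limits", {
  ec <- elastic_constants()
  # straight twisted rod: (C/2) t^2
  for (t in c(0.1, 1, 5)) {
    expect_equal(landau_free_energy_density(0, 0, 0, t, ec),
                 (ec$C_red / 2) * t^2)
  }
  # planar bend at theta = pi/2: (B/2) kappa^2
  for (kappa in c(0.2, 2)) {
    expect_equal(landau_free_energy_density(pi / 2, 0, kappa, 0, ec),
                 (ec$B_red / 2) * kappa^2)
  }
  # SI units scale by kB T relative to reduced
  expect_equal(landau_free_energy_density(1, 0.5, 0.3, 0.2, ec, units = "si"),
               landau_free_energy_density(1, 0.5, 0.3, 0.2, ec) * ec$kB * 300)
})

test_that("Euler density is non-negative and shift-invariant in phi and chi", {
  ec <- elastic_constants()
  set.seed(303)
  for (i in 1:200) {
    theta <- runif(1, 1e-3, pi - 1e-3)
    d <- runif(3, -5, 5)
    f <- landau_free_energy_density(theta, d[1], d[2], d[3], ec)
    expect_gte(f, 0)
  }
  # only derivatives enter: the density at mapped angle values is unchanged
  # when constant offsets are added to phi and chi along a path
  s <- seq(0, 2, length.out = 41)
  base <- euler_path(s, phi = 1.3 * s, theta = rep(1.1, 41), chi = -0.4 * s)
  shifted <- euler_path(s, phi = 1.3 * s + 5, theta = rep(1.1, 41),
                        chi = -0.4 * s - 2)
  expect_equal(
    landau_free_energy_density(base$theta, base$dtheta, base$dphi, base$dchi, ec),
    landau_free_energy_density(shifted$theta, shifted$dtheta, shifted$dphi,
                               shifted$dchi, ec)
  )
})

test_that("torsion combines the Euler rates as dphi cos(theta) + dchi", {
  expect_identical(torsion(0, 1.2, 3), 3)
  expect_equal(torsion(5, pi / 2, 0), 0)
  expect_identical(torsion(2, 0, 3), 5)
})

test_that("twist of a constant-torsion path is tau L / (2 pi)", {
  n <- 201
  s <- seq(0, 3, length.out = n)
  p <- euler_path(s, phi = rep(0, n), theta = rep(pi / 2, n), chi = 1.7 * s)
  expect_equal(twist_number(p), 1.7 * 3 / (2 * pi))
  # constructed to give the nucleosomal twist 15.75 over unit length
  tau0 <- 2 * pi * 15.75
  p2 <- euler_path(seq(0, 1, length.out = n), phi = rep(0, n),
                   theta = rep(pi / 2, n),
                   chi = tau0 * seq(0, 1, length.out = n))
  expect_equal(twist_number(p2), 15.75)
})

test_that("twist quadrature converges at second order on smooth paths", {
  tw_at <- function(n) {
    s <- seq(0, 2, length.out = n)
    phi <- sin(s); theta <- 1 + 0.3 * cos(s); chi <- 0.5 * s + 0.2 * sin(2 * s)
    p <- euler_path(s, phi, theta, chi,
                    dphi = cos(s), dtheta = -0.3 * sin(s),
                    dchi = 0.5 + 0.4 * cos(2 * s))
    twist_number(p)
  }
  # reference: 100x refined grid
  ref <- tw_at(32001)
  err_coarse <- abs(tw_at(321) - ref)
  expect_lt(err_coarse / abs(ref), 1e-6)
  # halving the spacing divides the error by ~4
  err_fine <- abs(tw_at(641) - ref)
  expect_gt(err_coarse / err_fine, 3.4)
  expect_lt(err_coarse / err_fine, 4.6)
})

test_that("euler_path validates its grid and fills derivatives", {
  expect_error(euler_path(1, 0, 1, 0), "at least 2")
  expect_error(euler_path(c(0, 0), c(0, 0), c(1, 1), c(0, 0)), "increasing")
  expect_error(euler_path(c(0, 1), c(0, 0), c(0, pi / 2), c(0, 0)),
               "inside")
  s <- seq(0, 1, length.out = 11)
  p <- euler_path(s, phi = 2 * s, theta = rep(1, 11), chi = -s)
  expect_equal(p$dphi, rep(2, 11))
  expect_equal(p$dchi, rep(-1, 11))
  expect_equal(p$dtheta, rep(0, 11))
})
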