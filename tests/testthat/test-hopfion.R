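ec <- elastic_constants()

test_that("angle mapping is linear with theta pinned at 2R", {
  out <- map_angles(pi / 8, p = 2, q = 7, phi_coord = 0, theta_coord = 0)
  expect_equal(out$theta, pi / 4)
  expect_equal(out$phi, 0)
  expect_equal(out$chi, 0)
  out <- map_angles(pi / 8, p = 1, q = 1, phi_coord = 0.3, theta_coord = 0.9)
  expect_equal(out$phi, 1.2)
  expect_equal(out$chi, -0.6)
  rates <- map_angle_rates(p = 3, q = 5, m = 2, n = 0.5)
  expect_identical(rates$dtheta, 0)
  expect_equal(rates$dphi, 3 * 2 + 5 * 0.5)
  expect_equal(rates$dchi, 3 * 2 - 5 * 0.5)
  expect_error(map_angles(0, 1, 1), "open interval")
  expect_error(map_angles(pi / 2, 1, 1), "open interval")
})

test_that("closed form reproduces the canonical nucleosome minima", {
  expect_equal(round(hopfion_free_energy(2.1, w = 14, r_deg = 22)), 1071)
  expect_equal(round(hopfion_free_energy(1.9, w = 14, r_deg = 18)), 938)
})

test_that("closed form equals the Euler-angle density on the mapped rates", {
  set.seed(2024)
  for (i in 1:300) {
    p <- runif(1, 0.3, 20)
    w <- runif(1, 1, 30)
    r_deg <- runif(1, 1, 89)
    m <- runif(1, -2, 2)
    n <- runif(1, -2, 2)
    closed <- hopfion_free_energy(p, w, r_deg, m, n, ec)
    via_euler <- oracle_energy_via_euler(p, w, r_deg, m, n,
                                         B = ec$B_red, C = ec$C_red)
    expect_lt(abs(closed - via_euler) / max(abs(via_euler), 1e-12), 1e-9)
    # and through the package's own general density
    rates <- map_angle_rates(p, w / p, m, n)
    general <- landau_free_energy_density(2 * r_deg * pi / 180, rates$dtheta,
                                          rates$dphi, rates$dchi, ec)
    expect_lt(abs(closed - general) / max(abs(general), 1e-12), 1e-9)
  }
})

test_that("free energy respects the small- and large-R limits", {
  for (p in c(0.7, 2, 9)) {
    for (m in c(0.5, 1)) {
      w <- 14
      q <- w / p
      # R -> 0: pure toroidal torsion 2C (Pm)^2
      expect_equal(hopfion_free_energy(p, w, 1e-6, m, 1, ec),
                   2 * ec$C_red * (p * m)^2, tolerance = 1e-6)
      # R -> 90: pure poloidal torsion 2C (Qn)^2
      expect_equal(hopfion_free_energy(p, w, 90 - 1e-6, m, 1, ec),
                   2 * ec$C_red * (q * 1)^2, tolerance = 1e-6)
    }
  }
})

test_that("free energy is invariant under the toroidal-poloidal duality swap", {
  set.seed(909)
  for (i in 1:100) {
    p <- runif(1, 0.3, 10)
    q <- runif(1, 0.3, 10)
    w <- p * q
    r_deg <- runif(1, 1, 89)
    m <- runif(1, -2, 2)
    n <- runif(1, -2, 2)
    f1 <- hopfion_free_energy(p, w, r_deg, m, n, ec)
    f2 <- hopfion_free_energy(q, w, 90 - r_deg, n, m, ec)
    expect_equal(f1, f2, tolerance = 1e-12)
  }
})

test_that("hopfion_config validates the factorization and accepts the density", {
  cfg <- hopfion_config(14, 2, r_deg = 20)
  expect_equal(cfg$q, 7)
  expect_equal(hopfion_free_energy(cfg),
               hopfion_free_energy(2, 14, 20))
  expect_error(hopfion_config(14, 2, q = 3, r_deg = 20), "equal")
  expect_error(hopfion_config(14, 2, r_deg = 95), "open interval")
  expect_error(hopfion_free_energy(-1, 14, 20), "positive")
})

test_that("total energy is linear in the reduced length", {
  expect_identical(total_energy(1071, 0), 0)
  expect_identical(total_energy(1071, 1), 1071)
  expect_equal(total_energy(938, 4), 2 * total_energy(938, 2))
  expect_error(total_energy(10, -1), "non-negative")
})

test_that("profile scan finds the printed grid minima and refines them", {
  pr22 <- energy_profile(14, 22)
  expect_equal(pr22$p_min_grid, 2.1)
  expect_equal(round(pr22$f_min_grid), 1071)
  pr18 <- energy_profile(14, 18)
  expect_equal(pr18$p_min_grid, 1.9)
  expect_equal(round(pr18$f_min_grid), 938)
  expect_equal(nrow(pr22$grid), 136)
  expect_true(all(pr22$grid$f >= 0))
  expect_lte(pr22$f_min, pr22$f_min_grid + 1e-9)

  # refined argmin against a dense brute-force scan
  for (r_deg in c(18, 20, 22)) {
    pr <- energy_profile(14, r_deg)
    dense <- seq(0.5, 14, by = 1e-4)
    fd <- hopfion_free_energy(dense, 14, r_deg)
    expect_lt(abs(pr$p_min - dense[which.min(fd)]), 1e-3)
    expect_lte(pr$f_min, min(fd) + 1e-9)
  }
  expect_error(energy_profile(14, 20, p_start = 5, p_stop = 2), "below")
})

test_that("minimum value and argmin increase with the bending angle R", {
  prof <- lapply(c(18, 20, 22), function(r) energy_profile(14, r))
  fmins <- vapply(prof, `[[`, 0, "f_min")
  pmins <- vapply(prof, `[[`, 0, "p_min")
  expect_true(all(diff(fmins) > 0))
  expect_true(all(diff(pmins) > 0))
})

test_that("minimum value increases with the linking number at fixed R", {
  fmins <- vapply(c(6, 14, 16, 18), function(w)
    energy_profile(w, 20)$f_min, 0)
  expect_true(all(diff(fmins) > 0))
})

test_that("integer minimum picks P = 2 for the canonical nucleosome", {
  im <- integer_minimum(14, 20)
  expect_equal(im$p_best, 2)
  expect_equal(im$candidates$p, c(1, 2, 7, 14))
  im1 <- integer_minimum(1, 30)
  expect_equal(im1$p_best, 1)
  # exhaustive check for a charge with six divisors
  im12 <- integer_minimum(12, 20)
  f_all <- hopfion_free_energy(c(1, 2, 3, 4, 6, 12), 12, 20)
  expect_equal(im12$p_best, c(1, 2, 3, 4, 6, 12)[which.min(f_all)])
  expect_equal(im12$f_best, min(f_all))
})
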