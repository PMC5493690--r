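test_that("mixing angle matches its arctangent definition and limits", {
  expect_equal(mixing_angle(0, 1e9), 0)
  expect_equal(mixing_angle(1e6, 1e6), pi / 8)
  expect_equal(mixing_angle(1e3, 1e6), 0.5 * atan(1e-3))
  # symmetric double well: theta -> pi/4 as the asymmetry vanishes
  expect_equal(mixing_angle(1e6, 0), pi / 4)
  expect_error(mixing_angle(0, 0), "undefined")
  expect_error(mixing_angle(-1, 1e6), "non-negative")
  # monotone increasing in omega_x at fixed omega_z, bounded by pi/4
  th <- mixing_angle(log_grid(1e3, 1e12, 30), 1e9)
  expect_true(all(diff(th) > 0))
  expect_true(all(th > 0 & th < pi / 4))
})

test_that("odorant constructor validates inputs and derives splitting", {
  od <- odorant_two_level(1e6, 1e9)
  expect_s3_class(od, "odorant_two_level")
  expect_equal(od$splitting, 2 * sqrt(1e12 + 1e18))
  expect_equal(od$theta, mixing_angle(1e6, 1e9))
  expect_error(odorant_two_level(0, 0), "degenerate")
  expect_error(odorant_two_level(-1e6, 1e9))
  expect_warning(odorant_two_level(1e13, 1e12), "1e12")
  expect_silent(odorant_two_level(1e13, 1e12, warn = FALSE))
})

test_that("WKB tunneling frequency has the stated scalings", {
  g <- function(V0, M = 1e-26) double_well_geometry(V0, omega_0 = 1e13,
                                                    M = M, q0 = 1e-10)
  # exponential suppression by the barrier
  expect_equal(wkb_tunneling_frequency(g(700 * 1e13)), 0, tolerance = 1e-200)
  # vanishing barrier: prefactor only
  expect_equal(wkb_tunneling_frequency(g(0)), 1e-10 * sqrt(1e-26 * 1e13))
  # sqrt-mass scaling
  expect_equal(wkb_tunneling_frequency(g(5e13, M = 2e-26)) /
                 wkb_tunneling_frequency(g(5e13, M = 1e-26)), sqrt(2))
  # strictly decreasing in V0
  w <- vapply(c(1, 2, 5, 10) * 1e13, function(v) wkb_tunneling_frequency(g(v)),
              numeric(1))
  expect_true(all(diff(w) < 0))
  expect_error(double_well_geometry(-1, 1e13, 1e-26, 1e-10), "non-negative")
  expect_false(g(2e13)$two_level_valid)
  expect_true(g(5e13)$two_level_valid)
})

test_that("default electronic parameters follow the odorant's natural frequency", {
  od <- odorant_two_level(1e6, 1e9)
  p <- default_electronic_parameters(od)
  om <- sqrt(1e12 + 1e18)
  expect_equal(p$eps, om)
  expect_equal(p$delta, 0.01 * om)
  expect_equal(p$gamma_D, 0.1 * om)
  # antisymmetric couplings for every odorant
  for (wx in c(0, 1e3, 1e9, 1e12)) {
    pp <- default_electronic_parameters(odorant_two_level(wx, 1e9))
    expect_identical(pp$gamma_D + pp$gamma_A, 0)
  }
  p0 <- default_electronic_parameters(odorant_two_level(0, 1e9))
  expect_equal(p0$eps, 1e9)
})

test_that("electronic parameters accept site energies consistently", {
  p <- electronic_parameters(eps_D = 3e9, eps_A = 2e9, delta = 1e7,
                             gamma_D = 1e8, gamma_A = -1e8)
  expect_equal(p$eps, 1e9)
  expect_error(electronic_parameters(eps = 5e8, eps_D = 3e9, eps_A = 2e9,
                                     delta = 1e7, gamma_D = 0, gamma_A = 0),
               "inconsistent")
  expect_true(weak_coupling_ok(p, bath_spectrum(cutoff = 1e12)))
  expect_false(weak_coupling_ok(p, bath_spectrum(cutoff = 1e8)))
})

test_that("polaron shifts match their closed form and limits", {
  # no coupling, no tunneling: both shifts at -omega_z/2
  od <- odorant_two_level(0, 1e6)
  p0 <- electronic_parameters(eps = 1e6, delta = 1e4, gamma_D = 0, gamma_A = 0)
  eta <- polaron_shifts(od, p0)
  expect_equal(unname(eta), c(-5e5, -5e5))
  # worked case: antisymmetric couplings make the shifts coincide
  od1 <- odorant_two_level(1e3, 1e6)
  p1 <- electronic_parameters(eps = 1e6, delta = 1e4, gamma_D = 1e5,
                              gamma_A = -1e5)
  eta1 <- polaron_shifts(od1, p1)
  expected <- -5e5 * cos(atan((1e3 - 1e5) / 1e6))
  expect_equal(unname(eta1["eta_D"]), expected)
  expect_equal(unname(eta1["eta_A"]), expected)
  expect_equal(expected, -4.9757e5, tolerance = 1e-4)
  # diverging argument: shift vanishes
  od2 <- odorant_two_level(1e12, 1e3, warn = FALSE)
  eta2 <- polaron_shifts(od2, default_electronic_parameters(od2))
  expect_lt(abs(eta2["eta_D"]), 1e3 * 1e-8)
  # range invariant over a parameter loop
  for (wx in c(0, 1e5, 1e9)) for (wz in c(1e6, 1e9)) {
    odi <- odorant_two_level(wx, wz)
    ei <- polaron_shifts(odi, default_electronic_parameters(odi))
    expect_true(all(ei >= -wz / 2 & ei <= 0))
  }
})

test_that("polaron mixing angle reduces to 2*theta without couplings", {
  for (wx in c(0, 1e3, 1e6, 1e9)) {
    od <- odorant_two_level(wx, 1e6)
    p <- electronic_parameters(eps = 1e6, delta = 1e4, gamma_D = 0, gamma_A = 0)
    expect_equal(polaron_mixing_angle(od, p), 2 * od$theta)
  }
  # worked case from the antisymmetric default couplings
  od <- odorant_two_level(1e6, 1e6)
  p <- electronic_parameters(eps = sqrt(2) * 1e6, delta = sqrt(2) * 1e4,
                             gamma_D = 1.41421e5, gamma_A = -1.41421e5)
  expect_equal(polaron_mixing_angle(od, p), atan((1e6 - 1.41421e5) / 1e6))
  # omega_x = 0 with antisymmetric couplings
  od0 <- odorant_two_level(0, 1e6)
  p0 <- electronic_parameters(eps = 1e6, delta = 1e4, gamma_D = 1e5,
                              gamma_A = -1e5)
  expect_equal(polaron_mixing_angle(od0, p0), atan(-1e5 / 1e6))
  # monotone in omega_x at fixed couplings
  ups <- vapply(log_grid(1e3, 1e12, 20), function(wx) {
    polaron_mixing_angle(odorant_two_level(wx, 1e9), p0)
  }, numeric(1))
  expect_true(all(diff(ups) > 0))
})

test_that("propagator matrix is a phase-dressed rotation with unit columns", {
  od <- odorant_two_level(1e6, 1e9)
  pr <- default_electronic_parameters(od)
  fr <- polaron_frame(od, pr)
  m0 <- omega_matrix(0, od, pr, fr)
  expect_equal(Im(m0), matrix(0, 2, 2))
  expect_equal(Re(m0), matrix(c(cos(fr$upsilon), -sin(fr$upsilon),
                                sin(fr$upsilon), cos(fr$upsilon)), 2, 2))
  for (t in c(0, 1e-13, 3e-12, 1e-9)) {
    m <- omega_matrix(t, od, pr, fr)
    expect_equal(colSums(Mod(m)^2), c(1, 1))
    expect_equal(Mod(m[1, 1]), abs(cos(fr$upsilon)))
  }
})
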